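#' Boxplot of per-practitioner accuracy estimates by strategy
#'
#' Convenience figure mirroring the content of the usual strategy
#' comparison boxplots: per-practitioner accuracy (or inner-mean) values
#' per method, grouped by strategy, with the ground-truth mean drawn as a
#' horizontal reference per method. Requires ggplot2.
#'
#' @param bundle a `result_bundle` from [run_metasimulation()].
#' @return a ggplot object.
#' @export
plot_strategy_comparison <- function(bundle) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  strategies <- c(list(prac = bundle$prac), bundle$sl)
  df <- do.call(rbind, lapply(names(strategies), function(s) {
    m <- strategies[[s]]$per_practitioner
    data.frame(strategy = s,
               method = rep(rownames(m), ncol(m)),
               value = as.vector(m))
  }))
  ref <- data.frame(method = names(bundle$truth$mu),
                    mu_true = unname(bundle$truth$mu))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$mu_true),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "estimated accuracy")
}
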