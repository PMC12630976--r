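#' Read a discrete Bayesian network from a BIF file
#'
#' Parses the Bayesian Interchange Format (0.15 dialect) as distributed in
#' the common public network repositories: `network`, `variable` and
#' `probability` blocks, `property` lines ignored, and both probability
#' notations accepted — per-configuration rows `(lvl1, lvl2) p1, p2;` and
#' flat `table p1, p2, ...;` rows. For a `table` row with parents the
#' entries are laid out with the child's levels varying fastest and the
#' last-listed parent's levels varying slowest (the JavaBayes convention).
#' Variable order and level order are preserved from the file.
#'
#' @param path path to a `.bif` file.
#' @param tol CPT rows must sum to 1 within this tolerance (default 1e-4;
#'   repository files are printed with few digits). Rows are renormalised
#'   after the check.
#' @return a [bayesian_network()].
#' @seealso [write_bif()]
#' @export
read_bif <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  txt <- gsub("/\\*.*?\\*/", "", txt, perl = TRUE)

  # map character offsets back to line numbers for error messages
  nl_pos <- gregexpr("\n", txt, fixed = TRUE)[[1]]
  line_of <- function(pos) 1L + sum(nl_pos > 0 & nl_pos < pos)

  var_names <- character(0)
  levels <- list()
  m <- gregexpr(
    "variable\\s+([A-Za-z0-9_.-]+)\\s*\\{([^}]*)\\}", txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      block <- regmatches(txt, list(m))[[1]][i]
      name <- regmatches(block,
        regexpr("variable\\s+\\K[A-Za-z0-9_.-]+", block, perl = TRUE))
      ty <- regmatches(block,
        regexpr("type\\s+discrete\\s*\\[\\s*\\d+\\s*\\]\\s*\\{[^}]*\\}",
                block, perl = TRUE))
      if (length(ty) == 0)
        stop("malformed variable block for '", name, "' near line ",
             line_of(m[i]), ": missing 'type discrete' declaration")
      lv <- sub(".*\\{([^}]*)\\}.*", "\\1", ty, perl = TRUE)
      lv <- trimws(strsplit(lv, ",")[[1]])
      lv <- lv[lv != ""]
      if (anyDuplicated(lv))
        stop("duplicate levels for variable '", name, "' near line ", line_of(m[i]))
      var_names <- c(var_names, name)
      levels[[name]] <- lv
    }
  }
  if (length(var_names) == 0) stop("no variable blocks found in ", path)

  cpts <- list()
  edges <- NULL
  pm <- gregexpr(
    "probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}", txt, perl = TRUE)[[1]]
  if (pm[1] == -1) stop("no probability blocks found in ", path)
  blocks <- regmatches(txt, list(pm))[[1]]
  for (i in seq_along(blocks)) {
    block <- blocks[i]
    ln <- line_of(pm[i])
    head_ <- regmatches(block, regexpr("\\([^)]*\\)", block))
    head_ <- substr(head_, 2, nchar(head_) - 1)
    parts <- strsplit(head_, "\\|")[[1]]
    child <- trimws(parts[1])
    parents <- if (length(parts) > 1)
      trimws(strsplit(parts[2], ",")[[1]]) else character(0)
    if (!child %in% var_names)
      stop("probability block near line ", ln,
           " refers to undeclared variable '", child, "'")
    if (!all(parents %in% var_names))
      stop("probability block for '", child, "' near line ", ln,
           " has undeclared parent(s)")
    body <- sub("^[^{]*\\{", "", block)
    body <- sub("\\}[^}]*$", "", body)
    kc <- length(levels[[child]])
    plev <- levels[parents]
    cards <- lengths(plev)
    n_cfg <- if (length(parents) == 0) 1L else prod(cards)
    prob <- matrix(NA_real_, n_cfg, kc)

    stmts <- trimws(strsplit(body, ";")[[1]])
    stmts <- stmts[stmts != ""]
    for (st in stmts) {
      if (grepl("^property\\b", st)) next
      if (grepl("^(table|default)\\b", st)) {
        vals <- suppressWarnings(as.numeric(
          trimws(strsplit(sub("^(table|default)", "", st), ",")[[1]])))
        if (anyNA(vals) || length(vals) != n_cfg * kc)
          stop("malformed table row for '", child, "' near line ", ln)
        # child fastest, last parent slowest -> configuration r (our order,
        # first parent fastest) sits at offset computed below
        if (length(parents) == 0) {
          prob[1, ] <- vals
        } else {
          for (r in seq_len(n_cfg)) {
            codes <- arrayInd(r, .dim = cards)  # first parent fastest
            off <- 0
            for (j in seq_along(cards))        # first parent slowest in file
              off <- off * cards[j] + (codes[j] - 1L)
            prob[r, ] <- vals[off * kc + seq_len(kc)]
          }
        }
      } else if (grepl("^\\(", st)) {
        cfg_lab <- trimws(strsplit(sub("^\\(([^)]*)\\).*", "\\1", st,
                                       perl = TRUE), ",")[[1]])
        if (length(cfg_lab) != length(parents))
          stop("malformed configuration row for '", child, "' near line ", ln)
        codes <- mapply(function(l, lv) match(l, lv), cfg_lab, plev)
        if (anyNA(codes))
          stop("unknown parent level in row for '", child, "' near line ", ln)
        r <- 1L + sum((codes - 1L) * cumprod(c(1, cards))[seq_along(cards)])
        vals <- suppressWarnings(as.numeric(
          trimws(strsplit(sub("^\\([^)]*\\)", "", st), ",")[[1]])))
        if (anyNA(vals) || length(vals) != kc)
          stop("malformed probability row for '", child, "' near line ", ln)
        prob[r, ] <- vals
      } else {
        stop("unparseable statement in block for '", child,
             "' near line ", ln, ": '", substr(st, 1, 40), "'")
      }
    }
    if (anyNA(prob))
      stop("probability block for '", child, "' near line ", ln,
           " does not cover all parent configurations")
    bad <- abs(rowSums(prob) - 1) > tol
    if (any(bad))
      stop("CPT row for '", child, "' near line ", ln,
           " does not sum to 1 (off by ",
           format(max(abs(rowSums(prob) - 1))), ")")
    prob <- prob / rowSums(prob)
    cpts[[child]] <- cpt(child, parents, levels[[child]], plev, prob)
    if (length(parents) > 0) edges <- rbind(edges, cbind(parents, child))
  }
  missing_cpt <- setdiff(var_names, names(cpts))
  if (length(missing_cpt) > 0)
    stop("no probability block for variable(s): ",
         paste(missing_cpt, collapse = ", "))
  dag <- dag_structure(var_names, edges)
  # bayesian_network() wants parents in sorted order
  cpts <- lapply(cpts, function(ct) align_cpt_parents(ct, sort(ct$parents)))
  bayesian_network(dag, levels, cpts)
}

#' Write a Bayesian network to a BIF file
#'
#' Emits the 0.15 dialect accepted by [read_bif()]: one `variable` block per
#' node in declaration order and one `probability` block per node — `table`
#' rows for parent-free nodes, per-configuration `( ... )` rows otherwise.
#' The written file re-parses to a network equal to the input.
#'
#' @param bn a [bayesian_network()].
#' @param path output file path.
#' @param digits digits printed per probability (default 10).
#' @return `path`, invisibly.
#' @export
write_bif <- function(bn, path, digits = 10) {
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  out <- c("network unknown {", "}")
  for (nd in bn$nodes) {
    lv <- bn$levels[[nd]]
    out <- c(out,
      sprintf("variable %s {", nd),
      sprintf("  type discrete [ %d ] { %s };", length(lv),
              paste(lv, collapse = ", ")),
      "}")
  }
  for (nd in bn$nodes) {
    ct <- bn$cpts[[nd]]
    if (length(ct$parents) == 0) {
      out <- c(out,
        sprintf("probability ( %s ) {", nd),
        sprintf("  table %s;", paste(fmt(ct$prob[1, ]), collapse = ", ")),
        "}")
    } else {
      grid <- do.call(expand.grid,
                      c(ct$parent_levels, stringsAsFactors = FALSE))
      rows <- vapply(seq_len(nrow(ct$prob)), function(r) {
        sprintf("  (%s) %s;",
                paste(unlist(grid[r, ]), collapse = ", "),
                paste(fmt(ct$prob[r, ]), collapse = ", "))
      }, character(1))
      out <- c(out,
        sprintf("probability ( %s | %s ) {", nd,
                paste(ct$parents, collapse = ", ")),
        rows, "}")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
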