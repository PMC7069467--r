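# Between-group edge-wise difference networks at snapshot latencies and the
# Pearson association of graph properties with CRS-R scores.

#' Edge-wise between-group test at a snapshot latency
#'
#' For every directed off-diagonal edge, a two-tailed Welch t-test of the
#' trial-averaged edge weights across the subjects of two groups at the
#' network time point nearest the requested latency. Edges with `p < alpha`
#' are retained (uncorrected by default, matching the P < 0.05 retention
#' convention of edge-wise time-varying network comparisons; set
#' `fdr = TRUE` for a Benjamini-Hochberg-corrected variant).
#'
#' @param groupA,groupB Lists of per-subject `tv_network` objects.
#' @param time_ms Snapshot latency in ms.
#' @param alpha Retention threshold, default 0.05.
#' @param fdr If `TRUE`, retain edges by BH-adjusted p-values instead.
#' @return A `diff_network`: data frame `edges` (`source`, `sink`, `t`, `p`,
#'   `mean_diff`, `direction` in `{A>B, B>A}`) plus `time_ms`, `alpha` and
#'   group sizes.
#' @export
edge_group_test <- function(groupA, groupB, time_ms, alpha = 0.05, fdr = FALSE) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop_docnet("statistics", "each group needs at least 2 subjects")
  labels <- groupA[[1]]$channel_labels
  n <- dim(groupA[[1]]$w)[1]
  labels <- labels %||% paste0("ch", seq_len(n))

  XA <- t(vapply(groupA, function(net) as.vector(network_at(net, time_ms)), numeric(n * n)))
  XB <- t(vapply(groupB, function(net) as.vector(network_at(net, time_ms)), numeric(n * n)))

  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- apply(XA, 2, stats::var); vB <- apply(XB, 2, stats::var)
  se <- sqrt(vA / nA + vB / nB)
  df <- (vA / nA + vB / nB)^2 /
    (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  zero <- se == 0 | !is.finite(se)
  tval <- ifelse(zero, 0, (mA - mB) / se)
  pval <- ifelse(zero, 1, 2 * stats::pt(-abs(tval), df))

  sink_i <- rep(seq_len(n), times = n)    # column-major over w[sink, source]
  source_j <- rep(seq_len(n), each = n)
  offdiag <- sink_i != source_j
  keep <- if (fdr) {
    offdiag & stats::p.adjust(ifelse(offdiag, pval, NA), method = "BH") <= alpha
  } else {
    offdiag & pval < alpha
  }
  keep[is.na(keep)] <- FALSE
  edges <- data.frame(
    source = labels[source_j[keep]],
    sink = labels[sink_i[keep]],
    t = tval[keep],
    p = pval[keep],
    mean_diff = (mA - mB)[keep],
    direction = ifelse((mA - mB)[keep] > 0, "A>B", "B>A"),
    stringsAsFactors = FALSE
  )
  structure(list(edges = edges, time_ms = time_ms, alpha = alpha,
                 n_A = nA, n_B = nB, n_edges_tested = sum(offdiag),
                 fdr = fdr),
            class = "diff_network")
}

#' @export
print.diff_network <- function(x, ...) {
  cat(sprintf("<diff_network> t=%g ms: %d/%d edges retained at alpha=%g\n",
              x$time_ms, nrow(x$edges), x$n_edges_tested, x$alpha))
  invisible(x)
}

#' Difference networks at a series of snapshot latencies
#'
#' @param groupA,groupB Lists of per-subject `tv_network` objects.
#' @param times_ms Snapshot latencies, default `c(100, 200, 300, 600, 1000)`.
#' @param alpha,fdr Passed to [edge_group_test()].
#' @return Named list of `diff_network` objects, one per latency.
#' @export
snapshot_series <- function(groupA, groupB,
                            times_ms = c(100, 200, 300, 600, 1000),
                            alpha = 0.05, fdr = FALSE) {
  if (length(times_ms) == 0L) return(stats::setNames(list(), character(0)))
  out <- lapply(times_ms, function(tm) edge_group_test(groupA, groupB, tm,
                                                       alpha = alpha, fdr = fdr))
  names(out) <- paste0("t", times_ms)
  out
}

#' Is a specific directed edge retained in a difference network?
#'
#' @param dn A `diff_network`.
#' @param source,sink Channel labels of the directed edge (source -> sink).
#' @param direction Optional required direction (`"A>B"` or `"B>A"`).
#' @return `TRUE` if the edge was retained (with the required direction).
#' @export
edge_retained <- function(dn, source, sink, direction = NULL) {
  hit <- dn$edges$source == source & dn$edges$sink == sink
  if (!is.null(direction)) hit <- hit & dn$edges$direction == direction
  any(hit)
}

#' Serialize a difference network as a TSV edge list
#'
#' @param dn A `diff_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_network_tsv <- function(dn, path) {
  df <- dn$edges
  df$time_ms <- rep(dn$time_ms, nrow(df))
  utils::write.table(df[c("time_ms", "source", "sink", "t", "p", "mean_diff",
                          "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson association of network properties with clinical scores
#'
#' Pearson's r and the two-tailed p-value (t transform, n - 2 degrees of
#' freedom) between each network property and the CRS-R total, across
#' matched subjects.
#'
#' @param props Data frame with one row per subject and columns `C`, `L`,
#'   `Ge`, `Le` (any subset), e.g. from [properties_table()].
#' @param scores Numeric CRS-R totals, matched to the rows of `props`.
#' @return Data frame with `property`, `r`, `p`, `n`. A property with zero
#'   variance (or zero score variance) yields `NA` with a warning.
#' @export
pearson_association <- function(props, scores) {
  props <- as.data.frame(props)
  keep <- intersect(c("C", "L", "Ge", "Le"), names(props))
  if (length(keep) == 0L) stop_docnet("parameter", "props must contain C, L, Ge or Le")
  n <- nrow(props)
  if (n != length(scores)) stop_docnet("parameter", "props and scores must be matched")
  if (n < 3) stop_docnet("statistics", "need at least 3 subjects")
  rows <- lapply(keep, function(nm) {
    x <- props[[nm]]
    ok <- is.finite(x) & is.finite(scores)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(scores[ok]) == 0) {
      warn_docnet("property %s: correlation undefined (zero variance or too few finite values)", nm)
      return(data.frame(property = nm, r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- stats::cor.test(x[ok], scores[ok], method = "pearson")
    data.frame(property = nm, r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Collect per-subject properties into a table
#'
#' @param props_list List of `network_properties` (one per subject).
#' @param subject_id Optional subject identifiers.
#' @return Data frame with columns `subject_id`, `C`, `L`, `Ge`, `Le`.
#' @export
properties_table <- function(props_list, subject_id = NULL) {
  df <- data.frame(
    subject_id = subject_id %||% seq_along(props_list),
    C = vapply(props_list, `[[`, numeric(1), "C"),
    L = vapply(props_list, `[[`, numeric(1), "L"),
    Ge = vapply(props_list, `[[`, numeric(1), "Ge"),
    Le = vapply(props_list, `[[`, numeric(1), "Le"),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}
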