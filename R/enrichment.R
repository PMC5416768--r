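#' One-tailed Welch (unequal-variance) two-sample t-test
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite degrees
#' of freedom
#' df = (s1^2/n1 + s2^2/n2)^2 / ((s1^2/n1)^2/(n1-1) + (s2^2/n2)^2/(n2-1)),
#' and the p-value taken from a single prespecified tail: `"greater"` tests
#' whether the hit group mean exceeds the background mean, `"less"` the
#' reverse.
#'
#' @param hit_values numeric vector (>= 2 values) for the hit group.
#' @param background_values numeric vector (>= 2 values) for the background.
#' @param tail `"greater"` or `"less"`.
#' @return A list of class `welch_test`: `statistic`, `degrees_of_freedom`,
#'   `p_value`, `tail`, `mean_hit`, `mean_background`, `n_hit`,
#'   `n_background`.
#' @examples
#' welch_one_tailed(c(5, 6, 7), c(1, 2, 3, 4), "greater")
#' @export
welch_one_tailed <- function(hit_values, background_values,
                             tail = c("greater", "less")) {
  tail <- match.arg(tail)
  n1 <- length(hit_values)
  n2 <- length(background_values)
  if (n1 < 2L || n2 < 2L) {
    stop_rs("each group needs at least 2 values", "rs_degenerate")
  }
  v1 <- stats::var(hit_values)
  v2 <- stats::var(background_values)
  if (!is.finite(v1) || !is.finite(v2) || (v1 == 0 && v2 == 0)) {
    stop_rs("zero variance in both groups: Welch test undefined",
            "rs_degenerate")
  }
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(hit_values) - mean(background_values)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- if (tail == "greater") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df)
  }
  structure(list(statistic = t_stat, degrees_of_freedom = df, p_value = p,
                 tail = tail,
                 mean_hit = mean(hit_values),
                 mean_background = mean(background_values),
                 n_hit = n1, n_background = n2),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch one-tailed t-test (%s): t = %.4f, df = %.3f, p = %.4g\n",
              x$tail, x$statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  hit mean %.4g (n = %d) vs background mean %.4g (n = %d)\n",
              x$mean_hit, x$n_hit, x$mean_background, x$n_background))
  invisible(x)
}

# tail directions in which enrichment of expression-enhancing regulators is
# tested by default; these are configuration, reported alongside each result
default_directions <- c(out_degree = "greater", betweenness = "greater",
                        clustering = "less", eccentricity = "less",
                        hierarchy = "greater")

#' Topology enrichment of hit regulators vs the TF background
#'
#' For each requested topology metric, splits the network's transcription
#' factors into the hit set and the remaining TFs (the genome background)
#' and runs a one-tailed unequal-variance t-test in the stated direction.
#' Hits that are not TF nodes of the network (e.g. lost in ortholog mapping)
#' are reported and excluded. TFs for which a metric is undefined carry its
#' 0-by-convention value unless `drop_undefined = TRUE`; hierarchy is defined
#' for every TF. Raw one-tailed p-values are reported (matching the
#' convention of quoting uncorrected p per metric), with a Bonferroni column
#' added for transparency.
#'
#' @param net a [regnetwork].
#' @param hit_tfs character vector of hit TF identifiers (already mapped to
#'   the network's identifier space).
#' @param metrics metrics to test (see [node_metrics()]).
#' @param directions named character vector of tails per metric; defaults to
#'   higher out-degree, higher betweenness, lower clustering, lower
#'   eccentricity, higher hierarchy.
#' @param metrics_table optional precomputed [node_metrics()] table for
#'   `net` (saves recomputing expensive metrics across many hit sets).
#' @param background optional explicit background node-id set; defaults to
#'   all TFs of the network not in the hit set.
#' @param drop_undefined drop TFs with fewer than two neighbours from the
#'   clustering comparison instead of scoring them 0.
#' @return A data frame of class `topology_enrichment` with one row per
#'   metric: `metric`, `direction`, `n_hit`, `n_bg`, `mean_hit`, `mean_bg`,
#'   `t`, `df`, `p_one_tailed`, `p_bonferroni`. Attribute `unmatched_hits`
#'   lists hit ids without a TF node in the network.
#' @export
topology_enrichment <- function(net, hit_tfs,
                                metrics = c("out_degree", "betweenness",
                                            "clustering", "eccentricity",
                                            "hierarchy"),
                                directions = NULL,
                                metrics_table = NULL,
                                background = NULL,
                                drop_undefined = FALSE) {
  dirs <- default_directions
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), names(dirs))
    if (length(bad) > 0L || !all(directions %in% c("greater", "less"))) {
      stop_rs("`directions` must map known metrics to 'greater' or 'less'",
              "rs_invalid_parameter")
    }
    dirs[names(directions)] <- directions
  }
  if (is.null(metrics_table)) {
    metrics_table <- node_metrics(net, metrics = metrics)
  }
  missing_cols <- setdiff(metrics, names(metrics_table))
  if (length(missing_cols) > 0L) {
    stop_rs(sprintf("metrics table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "rs_invalid_parameter")
  }
  tf_tab <- metrics_table[metrics_table$is_tf, , drop = FALSE]

  hit_tfs <- unique(as.character(hit_tfs))
  unmatched <- setdiff(hit_tfs, tf_tab$node)
  if (length(unmatched) > 0L) {
    message(sprintf("%d hit id(s) have no TF node in the network and are excluded: %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 5L), collapse = ", ")))
  }
  hits <- intersect(hit_tfs, tf_tab$node)
  if (length(hits) == 0L) {
    stop_rs("no hits remain after matching to the network's TFs",
            "rs_empty_hits")
  }
  bg <- if (is.null(background)) {
    setdiff(tf_tab$node, hits)
  } else {
    setdiff(intersect(as.character(background), metrics_table$node), hits)
  }
  if (length(bg) < 2L || length(hits) < 2L) {
    stop_rs("need at least 2 hit TFs and 2 background TFs", "rs_degenerate")
  }
  value_tab <- if (is.null(background)) tf_tab else metrics_table

  rows <- lapply(metrics, function(m) {
    v <- stats::setNames(value_tab[[m]], value_tab$node)
    hv <- v[hits]
    bv <- v[bg]
    if (m == "clustering" && drop_undefined) {
      deg_all <- adjacency(net, "all")
      nb <- stats::setNames(vapply(deg_all$adj, length, integer(1)), deg_all$ids)
      hv <- hv[nb[names(hv)] >= 2]
      bv <- bv[nb[names(bv)] >= 2]
    }
    hv <- hv[!is.na(hv)]
    bv <- bv[!is.na(bv)]
    w <- welch_one_tailed(hv, bv, tail = dirs[[m]])
    data.frame(metric = m, direction = w$tail,
               n_hit = w$n_hit, n_bg = w$n_background,
               mean_hit = w$mean_hit, mean_bg = w$mean_background,
               t = w$statistic, df = w$degrees_of_freedom,
               p_one_tailed = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_one_tailed * length(metrics))
  rownames(out) <- NULL
  attr(out, "unmatched_hits") <- unmatched
  class(out) <- c("topology_enrichment", "data.frame")
  out
}

#' @export
print.topology_enrichment <- function(x, digits = 4, ...) {
  cat(sprintf("Topology enrichment: %d hit TF(s) vs %d background TF(s)\n",
              x$n_hit[1L], x$n_bg[1L]))
  df <- as.data.frame(x)
  df$mean_hit <- signif(df$mean_hit, digits)
  df$mean_bg <- signif(df$mean_bg, digits)
  df$t <- signif(df$t, digits)
  df$df <- signif(df$df, digits)
  df$p_one_tailed <- signif(df$p_one_tailed, digits)
  df$p_bonferroni <- signif(df$p_bonferroni, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
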