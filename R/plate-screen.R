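#' Growth-normalise a well signal
#'
#' Divides a well's raw signal (fluorescence AU or absorbance) by its culture
#' density reading (OD600 or A660) to correct for biomass differences. Wells
#' at or below the growth floor are refused with a classed error rather than
#' silently producing a blown-up ratio; pipeline callers exclude such wells
#' and report them.
#'
#' @param signal non-negative numeric vector.
#' @param growth positive numeric vector (recycled against `signal`).
#' @param floor minimum growth reading regarded as a viable culture
#'   (default 0.05 OD).
#' @return `signal / growth`, numeric.
#' @examples
#' growth_normalize(500, 0.5) # 1000
#' @export
growth_normalize <- function(signal, growth, floor = 0.05) {
  if (any(is.na(signal)) || any(signal < 0)) {
    stop_rs("`signal` must be non-negative", "rs_invalid_parameter")
  }
  if (any(is.na(growth)) || any(growth <= floor)) {
    n_low <- sum(is.na(growth) | growth <= floor)
    stop_rs(sprintf("%d well(s) at or below the growth floor (%.3g); exclude before normalising",
                    n_low, floor), "rs_low_growth")
  }
  signal / growth
}

#' Standardise values within one plate
#'
#' Subtracts the plate mean and divides by the plate sample standard
#' deviation (denominator n - 1), making clones comparable across plates.
#'
#' @param values numeric vector of growth-normalised signals from one plate
#'   (at least 3 values).
#' @return z-scores with mean 0 and sample SD 1, in input order.
#' @examples
#' plate_standardize(c(1, 2, 3)) # -1 0 1
#' @export
plate_standardize <- function(values) {
  if (length(values) < 3L) {
    stop_rs("need at least 3 wells per plate to standardise",
            "rs_insufficient_data")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop_rs("degenerate plate: zero standard deviation", "rs_degenerate_plate")
  }
  (values - mean(values)) / s
}

#' Select outlier clones from standardised scores
#'
#' Returns the clones whose z-score strictly exceeds the threshold. By
#' default only the high tail is selected (enhanced expression); set
#' `two_sided = TRUE` to also pick up strongly reduced expressors.
#'
#' @param z named numeric vector of z-scores (names are clone ids), or a data
#'   frame with columns `clone` and `z`.
#' @param threshold non-negative number of standard deviations.
#' @param two_sided select `|z| > threshold` instead of `z > threshold`.
#' @return Character vector of unique selected clone ids.
#' @export
select_outliers <- function(z, threshold, two_sided = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop_rs("`threshold` must be a single non-negative number",
            "rs_invalid_parameter")
  }
  if (is.data.frame(z)) {
    clones <- as.character(z$clone)
    z <- as.numeric(z$z)
  } else {
    clones <- names(z)
    if (is.null(clones)) clones <- as.character(seq_along(z))
  }
  keep <- if (two_sided) abs(z) > threshold else z > threshold
  unique(clones[keep])
}

#' Run the multi-round outlier-selection screen
#'
#' Implements the full hit-calling pipeline on plate measurements: per round,
#' growth-normalise each well, standardise within each plate, and select
#' clones above that round's threshold; survivors are intersected across
#' rounds (a hit must exceed every round's threshold), and the final
#' survivors are tallied by construct through the clone map. Default
#' thresholds are 2 SD in the primary screen and 1 SD in the repeat assay.
#'
#' Wells at or below the growth floor are excluded with a message. Plates
#' whose normalised signals are constant cannot be standardised; their wells
#' get z = 0 (hence are never selected) and a warning reports the count.
#' A prior survivor missing from a later round's data is treated as a failed
#' re-screen (dropped, with a warning), since only consistent outliers count.
#'
#' @param measurements data frame with columns `plate`, `well`, `clone`,
#'   `signal`, `growth`, `round` (round r data is used against
#'   `thresholds[r]`).
#' @param clone_map data frame with columns `clone`, `promoter`, `cds`
#'   identifying each clone's construct (the in-silico stand-in for Sanger
#'   sequencing of hits). Optional: without it the tally is skipped.
#' @param thresholds numeric vector of per-round selection thresholds (SD
#'   units); its length sets the number of rounds.
#' @param growth_floor minimum viable growth reading.
#' @param two_sided passed to [select_outliers()].
#' @return An object of class `hit_set`: list with `hits` (final surviving
#'   clone ids), `z` (data frame of per-round z-scores for every clone scored
#'   in round 1), `survivors` (list of per-round survivor sets), `thresholds`,
#'   and `tally` (data frame construct -> count among final hits, `NULL`
#'   without a clone map).
#' @export
run_screen_rounds <- function(measurements, clone_map = NULL,
                              thresholds = c(2, 1), growth_floor = 0.05,
                              two_sided = FALSE) {
  req <- c("plate", "well", "clone", "signal", "growth", "round")
  if (!all(req %in% names(measurements))) {
    stop_rs(sprintf("measurements must have columns %s",
                    paste(req, collapse = ", ")), "rs_invalid_parameter")
  }
  if (any(thresholds <= 0)) {
    stop_rs("thresholds must be positive", "rs_invalid_parameter")
  }
  n_rounds <- length(thresholds)
  survivors <- vector("list", n_rounds)
  zlist <- vector("list", n_rounds)
  current <- NULL
  n_degenerate <- 0L

  for (r in seq_len(n_rounds)) {
    dat <- measurements[measurements$round == r, , drop = FALSE]
    if (nrow(dat) == 0L) {
      survivors[[r]] <- character(0)
      current <- character(0)
      zlist[[r]] <- stats::setNames(numeric(0), character(0))
      next
    }
    low <- dat$growth <= growth_floor
    if (any(low)) {
      message(sprintf("round %d: excluding %d low-growth well(s)", r, sum(low)))
      dat <- dat[!low, , drop = FALSE]
    }
    norm <- growth_normalize(dat$signal, dat$growth, floor = growth_floor)
    # standardise everything measured in this round, plate by plate; whether
    # the round re-arrays only survivors or re-reads the whole library, the
    # plate mean/SD comes from what was actually on the plate
    z <- rep(NA_real_, nrow(dat))
    for (p in unique(dat$plate)) {
      i <- which(dat$plate == p)
      if (length(i) >= 3L && stats::sd(norm[i]) == 0) {
        n_degenerate <- n_degenerate + 1L
        z[i] <- 0
      } else {
        z[i] <- plate_standardize(norm[i])
      }
    }
    zr <- stats::setNames(z, dat$clone)
    zlist[[r]] <- zr
    sel <- select_outliers(zr, thresholds[r], two_sided = two_sided)
    if (r == 1L) {
      current <- sel
    } else {
      missing <- setdiff(current, dat$clone)
      if (length(missing) > 0L) {
        warning(sprintf("round %d: %d prior survivor(s) missing from the data; treated as failed re-screen",
                        r, length(missing)), call. = FALSE)
      }
      current <- intersect(current, sel)
    }
    survivors[[r]] <- current
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d constant plate(s) could not be standardised; their wells scored z = 0",
                    n_degenerate), call. = FALSE)
  }

  all_clones <- names(zlist[[1L]])
  zmat <- data.frame(clone = all_clones, stringsAsFactors = FALSE)
  for (r in seq_len(n_rounds)) {
    zmat[[paste0("z_round", r)]] <- unname(zlist[[r]][all_clones])
  }

  tally <- NULL
  if (!is.null(clone_map)) {
    cm <- as.data.frame(clone_map)
    if (!all(c("clone", "promoter", "cds") %in% names(cm))) {
      stop_rs("clone map must have columns clone, promoter, cds",
              "rs_invalid_parameter")
    }
    hit_rows <- cm[match(current, cm$clone), , drop = FALSE]
    if (anyNA(hit_rows$clone) && length(current) > 0L) {
      warning("some hits are missing from the clone map", call. = FALSE)
      hit_rows <- hit_rows[!is.na(hit_rows$clone), , drop = FALSE]
    }
    if (nrow(hit_rows) > 0L) {
      key <- paste0(hit_rows$promoter, "::", hit_rows$cds)
      tb <- table(key)
      first <- hit_rows[!duplicated(key), , drop = FALSE]
      ord <- order(-as.integer(tb[paste0(first$promoter, "::", first$cds)]),
                   first$promoter, first$cds)
      first <- first[ord, , drop = FALSE]
      tally <- data.frame(promoter = first$promoter, cds = first$cds,
                          construct = paste0(first$promoter, "::", first$cds),
                          count = as.integer(tb[paste0(first$promoter, "::",
                                                       first$cds)]),
                          stringsAsFactors = FALSE)
      rownames(tally) <- NULL
    } else {
      tally <- data.frame(promoter = character(0), cds = character(0),
                          construct = character(0), count = integer(0))
    }
  }

  structure(list(hits = current, z = zmat, survivors = survivors,
                 thresholds = thresholds, tally = tally),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("Screen hit set: %d clone(s) surviving %d round(s) (thresholds: %s SD)\n",
              length(x$hits), length(x$thresholds),
              paste(x$thresholds, collapse = ", ")))
  for (r in seq_along(x$survivors)) {
    cat(sprintf("  round %d: %d survivor(s)\n", r, length(x$survivors[[r]])))
  }
  if (!is.null(x$tally) && nrow(x$tally) > 0L) {
    cat("Construct tally:\n")
    print(x$tally[, c("construct", "count")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hit_set <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Fold change between rewired and control clones
#'
#' Ratio of group means, with a delta-method standard error propagated from
#' the two group standard errors:
#' SE(fold) = fold * sqrt((SE_r / mean_r)^2 + (SE_c / mean_c)^2).
#' The ratio-of-means form is used because control clones are not
#' biologically paired to specific rewired clones.
#'
#' @param rewired positive numeric vector of (growth-normalised) signals for
#'   the rewired clones.
#' @param control same for the control clones; the control mean must be
#'   positive.
#' @return A list with `fold`, `se`, `n_rewired`, `n_control`.
#' @export
fold_change <- function(rewired, control) {
  if (length(rewired) == 0L || length(control) == 0L) {
    stop_rs("both groups must be non-empty", "rs_invalid_parameter")
  }
  m_c <- mean(control)
  if (!is.finite(m_c) || m_c <= 0) {
    stop_rs("control mean must be positive", "rs_invalid_baseline")
  }
  m_r <- mean(rewired)
  fold <- m_r / m_c
  se_r <- if (length(rewired) > 1L) stats::sd(rewired) / sqrt(length(rewired)) else 0
  se_c <- if (length(control) > 1L) stats::sd(control) / sqrt(length(control)) else 0
  rel <- 0
  if (m_r > 0) rel <- (se_r / m_r)^2
  se <- abs(fold) * sqrt(rel + (se_c / m_c)^2)
  list(fold = fold, se = se,
       n_rewired = length(rewired), n_control = length(control))
}

#' Percent enhancement over a parent strain
#'
#' Convenience wrapper around [fold_change()]: reports
#' 100 * (fold - 1) with the matching standard error (100 * SE(fold)), the
#' form in which metabolite titre improvements are usually quoted.
#'
#' @inheritParams fold_change
#' @param parent signals of the parent (non-rewired) strain.
#' @return A list with `percent`, `se`, `n_rewired`, `n_parent`.
#' @export
percent_enhancement <- function(rewired, parent) {
  fc <- fold_change(rewired, parent)
  list(percent = 100 * (fc$fold - 1), se = 100 * fc$se,
       n_rewired = fc$n_rewired, n_parent = fc$n_control)
}

#' Paired two-sample t-test
#'
#' t = mean(d) / (SD(d) / sqrt(n)) on the paired differences d = x - y, with
#' n - 1 degrees of freedom. Pairs are matched by position in the two
#' vectors (in the validation assay, by plate-well position, which cancels
#' plate-location effects).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param tail `"two.sided"` (default), `"greater"` (x > y) or `"less"`.
#' @return An object of class `screen_t_test`: list with `statistic`,
#'   `degrees_of_freedom`, `p_value`, `tail`, `n`.
#' @export
paired_t_test <- function(x, y, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) {
    stop_rs("paired test needs equal-length vectors", "rs_pairing_error")
  }
  n <- length(x)
  if (n < 2L) stop_rs("need at least 2 pairs", "rs_insufficient_data")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    # identical vectors carry no evidence of a difference; zero-variance
    # differences with a nonzero mean leave t undefined
    if (all(d == 0)) {
      return(structure(list(statistic = 0, degrees_of_freedom = n - 1,
                            p_value = if (tail == "two.sided") 1 else 0.5,
                            tail = tail, n = n),
                       class = "screen_t_test"))
    }
    stop_rs("zero-variance differences: paired t-test undefined",
            "rs_degenerate")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(tail,
    two.sided = 2 * stats::pt(-abs(t_stat), df),
    greater = stats::pt(t_stat, df, lower.tail = FALSE),
    less = stats::pt(t_stat, df))
  structure(list(statistic = t_stat, degrees_of_freedom = df, p_value = p,
                 tail = tail, n = n),
            class = "screen_t_test")
}

#' @export
print.screen_t_test <- function(x, ...) {
  cat(sprintf("Paired t-test (%s): t = %.4f, df = %g, p = %.4g, n = %d pairs\n",
              x$tail, x$statistic, x$degrees_of_freedom, x$p_value, x$n))
  invisible(x)
}

#' Growth-corrected lycopene signal
#'
#' Relative lycopene content from culture absorbance: the A484 reading of a
#' diluted culture is scaled back by the dilution factor and corrected for
#' biomass with the A660 reading: `dilution * a484 / a660`. With
#' `dilution = 1` this reduces to plain growth normalisation.
#'
#' @param a484 absorbance at 484 nm of the diluted culture (non-negative).
#' @param a660 absorbance at 660 nm (growth proxy; must exceed the floor).
#' @param dilution dilution factor of the assayed culture (default 5, i.e.
#'   1:5).
#' @param floor growth floor, as in [growth_normalize()].
#' @return Relative lycopene content, arbitrary units.
#' @examples
#' lycopene_signal(0.4, 0.8, 5) # 2.5
#' @export
lycopene_signal <- function(a484, a660, dilution = 5, floor = 0.05) {
  dilution <- assert_positive(dilution, "dilution")
  dilution * growth_normalize(a484, a660, floor = floor)
}
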