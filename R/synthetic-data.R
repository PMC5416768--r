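#' Combinatorial promoter x CDS library design
#'
#' Builds the full ordered cross product of a promoter set and a regulator
#' CDS set: every promoter::CDS fusion the Gibson-style random assembly can
#' produce. With the default labels, identifiers are deterministic
#' (`P001..`, `C001..`).
#'
#' @param n_promoters,n_cds positive integers.
#' @param promoters,cds_ids optional explicit identifier vectors (unique,
#'   lengths matching the counts); useful when the CDSs must be real gene ids
#'   that exist in a regulatory network.
#' @return Object of class `library_design`: list with `promoters`,
#'   `cds_list`, and `constructs` (data frame `promoter`, `cds`, `construct`
#'   where `construct = promoter::cds`).
#' @examples
#' d <- make_library_design(67, 43)
#' nrow(d$constructs) # 2881
#' @export
make_library_design <- function(n_promoters, n_cds,
                                promoters = NULL, cds_ids = NULL) {
  n_promoters <- assert_count(n_promoters, "n_promoters")
  n_cds <- assert_count(n_cds, "n_cds")
  if (is.null(promoters)) promoters <- sprintf("P%03d", seq_len(n_promoters))
  if (is.null(cds_ids)) cds_ids <- sprintf("C%03d", seq_len(n_cds))
  if (length(promoters) != n_promoters || anyDuplicated(promoters)) {
    stop_rs("`promoters` must be n_promoters unique identifiers",
            "rs_invalid_parameter")
  }
  if (length(cds_ids) != n_cds || anyDuplicated(cds_ids)) {
    stop_rs("`cds_ids` must be n_cds unique identifiers",
            "rs_invalid_parameter")
  }
  grid <- expand.grid(cds = cds_ids, promoter = promoters,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("promoter", "cds")]
  grid$construct <- paste0(grid$promoter, "::", grid$cds)
  rownames(grid) <- NULL
  structure(list(promoters = promoters, cds_list = cds_ids,
                 constructs = grid),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("Rewiring library design: %d promoters x %d CDSs = %d constructs\n",
              length(x$promoters), length(x$cds_list), nrow(x$constructs)))
  invisible(x)
}

#' Ground truth for a simulated screen
#'
#' Bundles the true per-construct fold effects with the noise model of the
#' simulated plate reader. Constructs not named in `fold_effects` are
#' non-enhancers (fold 1). Well noise is multiplicative with the given
#' coefficient of variation; under the default `"lognormal"` model the noise
#' factor is exp(s Z - s^2/2) (mean exactly 1), under `"normal"` it is
#' 1 + cv Z, giving exactly Gaussian per-plate z-scores in the no-effect
#' limit. Plate batch effects are multiplicative lognormal with `plate_sd` on
#' the log scale; culture growth is lognormal around `growth_mean`.
#'
#' @param design a [make_library_design()] object.
#' @param fold_effects named numeric vector, construct id -> fold effect
#'   (strictly positive); missing constructs default to 1.
#' @param baseline baseline growth-normalised signal of a non-enhancer
#'   (arbitrary units).
#' @param well_cv well-to-well coefficient of variation of the signal.
#' @param plate_sd log-scale SD of the per-plate batch factor.
#' @param growth_mean,growth_cv mean and CV of culture density (OD600-like).
#' @param noise_model `"lognormal"` (default) or `"normal"`.
#' @return Object of class `screen_truth`.
#' @export
screen_ground_truth <- function(design, fold_effects = NULL, baseline = 1000,
                                well_cv = 0.2, plate_sd = 0.1,
                                growth_mean = 0.5, growth_cv = 0.2,
                                noise_model = c("lognormal", "normal")) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(design, "library_design"))
  constructs <- design$constructs$construct
  fold <- stats::setNames(rep(1, length(constructs)), constructs)
  if (!is.null(fold_effects)) {
    if (is.null(names(fold_effects)) ||
        !all(names(fold_effects) %in% constructs)) {
      stop_rs("`fold_effects` must be named by constructs of the design",
              "rs_invalid_parameter")
    }
    if (any(fold_effects <= 0)) {
      stop_rs("fold effects must be strictly positive", "rs_invalid_parameter")
    }
    fold[names(fold_effects)] <- fold_effects
  }
  structure(list(fold = fold,
                 baseline = assert_positive(baseline, "baseline"),
                 well_cv = well_cv, plate_sd = plate_sd,
                 growth_mean = assert_positive(growth_mean, "growth_mean"),
                 growth_cv = growth_cv, noise_model = noise_model),
            class = "screen_truth")
}

# multiplicative noise factor with mean 1 and coefficient of variation cv
noise_factor <- function(n, cv, model) {
  if (cv == 0) return(rep(1, n))
  if (model == "lognormal") {
    s <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -s^2 / 2, s))
  } else {
    1 + cv * stats::rnorm(n)
  }
}

# A01-style well labels for plates up to 26 rows of 12; beyond that, W%04d
make_well_ids <- function(n) {
  if (n <= 312L) {
    rows <- LETTERS[seq_len(ceiling(n / 12))]
    ids <- as.vector(t(outer(rows, sprintf("%02d", 1:12), paste0)))
    ids[seq_len(n)]
  } else {
    sprintf("W%04d", seq_len(n))
  }
}

#' Simulate a combinatorial rewiring plate screen
#'
#' Draws clones by uniform sampling of constructs with replacement (colony
#' picking), arrays them into plates, and for each screening round generates
#' one measurement per well:
#' `signal = baseline * fold * growth * plate_factor * well_noise`,
#' with growth itself lognormal, so that growth normalisation followed by
#' per-plate standardisation can undo exactly the structure that was put in.
#' Every clone is re-measured in every round (fresh growth, plate factor and
#' noise); clone identity and plate position are stable across rounds.
#' Output is fully determined by `seed`.
#'
#' @param design a [make_library_design()] object.
#' @param truth a [screen_ground_truth()] object for the same design.
#' @param coverage expected clones per construct; the screen emits
#'   `round(coverage * n_constructs)` clones.
#' @param wells_per_plate wells per plate (default 96).
#' @param n_rounds number of screening rounds to measure (default 2).
#' @param seed integer seed.
#' @return A list of class `screen_simulation`: `measurements` (data frame
#'   `plate`, `well`, `clone`, `signal`, `growth`, `round`), `clone_map`
#'   (data frame `clone`, `promoter`, `cds`, `construct`) and `seed`.
#' @export
simulate_screen <- function(design, truth, coverage = 2,
                            wells_per_plate = 96, n_rounds = 2, seed = 1) {
  stopifnot(inherits(design, "library_design"), inherits(truth, "screen_truth"))
  coverage <- assert_positive(coverage, "coverage")
  wells_per_plate <- assert_count(wells_per_plate, "wells_per_plate")
  n_rounds <- assert_count(n_rounds, "n_rounds")
  seed <- assert_seed(seed)

  n_constructs <- nrow(design$constructs)
  n_clones <- max(1L, round(coverage * n_constructs))
  set.seed(seed)
  pick <- sample.int(n_constructs, n_clones, replace = TRUE)

  n_plates <- ceiling(n_clones / wells_per_plate)
  plate <- sprintf("PL%03d", rep(seq_len(n_plates), each = wells_per_plate))[seq_len(n_clones)]
  well <- rep(make_well_ids(wells_per_plate), n_plates)[seq_len(n_clones)]
  clone <- paste0(plate, ":", well)

  clone_map <- data.frame(clone = clone,
                          promoter = design$constructs$promoter[pick],
                          cds = design$constructs$cds[pick],
                          construct = design$constructs$construct[pick],
                          stringsAsFactors = FALSE)
  fold <- unname(truth$fold[clone_map$construct])

  g_s <- sqrt(log(1 + truth$growth_cv^2))
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    plate_factor <- exp(stats::rnorm(n_plates, 0, truth$plate_sd))
    growth <- truth$growth_mean *
      exp(stats::rnorm(n_clones, -g_s^2 / 2, g_s))
    wn <- noise_factor(n_clones, truth$well_cv, truth$noise_model)
    signal <- truth$baseline * fold * growth *
      plate_factor[rep(seq_len(n_plates), each = wells_per_plate)[seq_len(n_clones)]] * wn
    signal <- pmax(signal, 0)
    rounds[[r]] <- data.frame(plate = plate, well = well, clone = clone,
                              signal = signal, growth = growth, round = r,
                              stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, rounds)
  rownames(measurements) <- NULL
  structure(list(measurements = measurements, clone_map = clone_map,
                 seed = seed),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat(sprintf("Simulated screen: %d clones on %d plate(s), %d round(s) (seed %d)\n",
              nrow(x$clone_map), length(unique(x$measurements$plate)),
              max(x$measurements$round), x$seed))
  invisible(x)
}

#' Simulate a heavy-tailed directed regulatory network
#'
#' Generates a TF -> target network emulating the hub-dominated shape of
#' ChIP-derived transcriptional networks at reduced size. Each TF's
#' out-degree is drawn from a heavy-tailed (Pareto-type) distribution scaled
#' so the mean out-degree per TF matches `mean_out_degree`; targets are then
#' chosen preferentially by current in-degree (rich-get-richer), producing
#' the hub structure that makes betweenness and out-degree contrasts
#' detectable. No self-loops are generated. Deterministic given `seed`.
#'
#' @param n_nodes total genes.
#' @param n_tfs number of TF nodes (the first `n_tfs` identifiers); must not
#'   exceed `n_nodes`.
#' @param mean_out_degree target mean number of targets per TF.
#' @param seed integer seed.
#' @return A [regnetwork] with node ids `G0001..` and `is_tf` true for the
#'   first `n_tfs` nodes.
#' @export
simulate_regnet <- function(n_nodes, n_tfs, mean_out_degree = 5, seed = 1) {
  n_nodes <- assert_count(n_nodes, "n_nodes")
  n_tfs <- assert_count(n_tfs, "n_tfs")
  mean_out_degree <- assert_positive(mean_out_degree, "mean_out_degree")
  seed <- assert_seed(seed)
  if (n_tfs > n_nodes) {
    stop_rs("n_tfs must not exceed n_nodes", "rs_invalid_parameter")
  }
  set.seed(seed)
  ids <- sprintf("G%04d", seq_len(n_nodes))
  tfs <- ids[seq_len(n_tfs)]

  # Pareto(alpha = 2) weights: heavy-tailed, finite mean; rescale so the
  # realised mean out-degree matches the request
  w <- (1 - stats::runif(n_tfs))^(-1 / 2)
  deg <- round(w * mean_out_degree / mean(w))
  deg <- pmin(pmax(deg, 1L), n_nodes - 1L)

  indeg <- rep(1, n_nodes) # +1 smoothing so every gene can be discovered
  from <- vector("list", n_tfs)
  order_tf <- sample.int(n_tfs)
  for (i in order_tf) {
    p <- indeg
    p[i] <- 0 # no self-loops
    tgt <- sample.int(n_nodes, deg[i], replace = FALSE, prob = p)
    from[[i]] <- tgt
    indeg[tgt] <- indeg[tgt] + 1
  }
  edges <- data.frame(
    from = rep(tfs, lengths(from)),
    to = ids[unlist(from)],
    stringsAsFactors = FALSE
  )
  regnetwork(edges, nodes = ids, tf_nodes = tfs)
}

#' Plant a hit-TF set with a known topological bias
#'
#' Ground truth for enrichment power studies: selects `k` TFs, mixing the
#' top-ranked TFs by a topology metric with uniform random picks. With
#' `bias = 1` the selection is exactly the top k by the metric (ties and
#' order broken by node id, so the set is deterministic); with `bias = 0` it
#' is a uniform random k-subset of the TFs; intermediate bias takes
#' `round(bias * k)` from the top of the ranking and the rest at random.
#'
#' @param net a [regnetwork].
#' @param metric_name one of `"out_degree"`, `"betweenness"`, `"clustering"`,
#'   `"eccentricity"`, `"hierarchy"`.
#' @param k number of TFs to select (at most the number of TFs).
#' @param bias number in \[0, 1\].
#' @param seed integer seed (used for the random component).
#' @return Sorted character vector of k TF identifiers.
#' @export
plant_hit_tfs <- function(net, metric_name, k, bias = 1, seed = 1) {
  k <- assert_count(k, "k")
  seed <- assert_seed(seed)
  if (!is.numeric(bias) || length(bias) != 1L || bias < 0 || bias > 1) {
    stop_rs("`bias` must be in [0, 1]", "rs_invalid_parameter")
  }
  tfs <- net$nodes[net$is_tf[net$nodes]]
  if (k > length(tfs)) {
    stop_rs("k exceeds the number of TFs", "rs_invalid_parameter")
  }
  vals <- node_metrics(net, metrics = metric_name)
  v <- stats::setNames(vals[[metric_name]], vals$node)[tfs]
  v[is.na(v)] <- -Inf
  ranked <- tfs[order(-v, tfs)]

  n_top <- round(bias * k)
  top <- ranked[seq_len(n_top)]
  set.seed(seed)
  rest_pool <- setdiff(tfs, top)
  rest <- if (k - n_top > 0L) sample(rest_pool, k - n_top) else character(0)
  sort(c(top, rest))
}

#' Simulate a paired rewired-vs-control validation assay
#'
#' Emulates the independent re-cloning validation: `n` rewired clones and
#' `n` control clones, paired by plate-well position (pairs share a plate,
#' hence a plate batch factor). The rewired clones carry a known fold
#' enhancement of growth-normalised signal. In `"fluorescence"` mode the
#' readout columns are GFP-like signal and OD; in `"absorbance"` mode they
#' are the A484 of a 1:`dilution` diluted culture and A660, laid out so that
#' [lycopene_signal()] recovers the growth-corrected content.
#'
#' @param n clones per group.
#' @param fold_effect true fold enhancement of the rewired clones.
#' @param baseline baseline growth-normalised signal (or lycopene content).
#' @param well_cv coefficient of variation of the multiplicative well noise.
#' @param plate_sd log-scale SD of the plate batch factor.
#' @param growth_mean,growth_cv culture density distribution.
#' @param mode `"fluorescence"` or `"absorbance"`.
#' @param dilution culture dilution factor in absorbance mode.
#' @param noise_model `"lognormal"` (default) or `"normal"`.
#' @param seed integer seed.
#' @return Data frame with one row per pair: `pair`, `plate`,
#'   `rewired_signal`, `rewired_growth`, `control_signal`, `control_growth`.
#' @export
simulate_validation_assay <- function(n = 44, fold_effect = 1,
                                      baseline = 1000, well_cv = 0.2,
                                      plate_sd = 0.1, growth_mean = 0.5,
                                      growth_cv = 0.2,
                                      mode = c("fluorescence", "absorbance"),
                                      dilution = 5,
                                      noise_model = c("lognormal", "normal"),
                                      seed = 1) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  n <- assert_count(n, "n")
  fold_effect <- assert_positive(fold_effect, "fold_effect")
  seed <- assert_seed(seed)
  set.seed(seed)

  pairs_per_plate <- 48L
  n_plates <- ceiling(n / pairs_per_plate)
  plate <- sprintf("PL%03d", rep(seq_len(n_plates), each = pairs_per_plate))[seq_len(n)]
  plate_factor <- exp(stats::rnorm(n_plates, 0, plate_sd))[rep(seq_len(n_plates),
                                                               each = pairs_per_plate)][seq_len(n)]
  g_s <- sqrt(log(1 + growth_cv^2))
  draw_growth <- function() growth_mean * exp(stats::rnorm(n, -g_s^2 / 2, g_s))
  g_r <- draw_growth()
  g_c <- draw_growth()
  s_r <- baseline * fold_effect * g_r * plate_factor * noise_factor(n, well_cv, noise_model)
  s_c <- baseline * g_c * plate_factor * noise_factor(n, well_cv, noise_model)
  if (mode == "absorbance") {
    s_r <- s_r / dilution
    s_c <- s_c / dilution
  }
  data.frame(pair = seq_len(n), plate = plate,
             rewired_signal = pmax(s_r, 0), rewired_growth = g_r,
             control_signal = pmax(s_c, 0), control_growth = g_c,
             stringsAsFactors = FALSE)
}
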