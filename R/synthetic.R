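#' Configuration for the synthetic construct-grid generator
#'
#' The generator emulates the statistical structure of a chimeric-VLP
#' solubility screen: a complete grid of `n_inserts` peptide inserts
#' crossed with `n_strategies` insertion strategies, where the class
#' label depends strongly on the insert and only weakly on the strategy.
#' Each construct's sequence is a constant N-flank, a strategy-specific
#' remnant of a scaffold core region carrying the insert, and a constant
#' C-flank; the flank lengths become the dataset's trim provenance.
#'
#' Labels derive from a latent score, the summed hydrophobicity of the
#' variable window under a designated "true" scale:
#' `latent = insert_effect_weight * feature(insert) +
#' strategy_effect_weight * feature(strategy core remnant)`.
#' A construct is soluble (1) when its latent score is below the
#' decision threshold.  Insert hydrophobicity sums are drawn from two
#' uniform bands (a hydrophilic/soluble and a hydrophobic/insoluble
#' mode) separated by an empty margin of `2 * class_margin` around the
#' threshold, and sequences are built to match the drawn sum; with
#' `label_noise = 0` the dataset is therefore perfectly separable by the
#' true scale's feature, which anchors recovery tests of the whole
#' pipeline.  Label noise flips each label independently with
#' probability `label_noise * strategy_noise_mult[s]`; by default the
#' last strategy is a designated "bad" strategy flipped at three times
#' the base rate, giving the weak strategy-level label effect.
#'
#' @param n_inserts,n_strategies Grid dimensions (defaults 71 and 8,
#'   i.e. 568 constructs).
#' @param insert_length Length range (residues) of the random peptide
#'   inserts.
#' @param flank_n,flank_c Lengths of the constant flanks (the trim
#'   provenance).
#' @param core_length Length of the scaffold core region that the
#'   strategies modify.
#' @param true_scale The label-generating scale: a [hydro_scale()], a
#'   scale id from [example_scale_library()], or `NULL` for
#'   Kyte-Doolittle (normalized and oriented).
#' @param insert_effect_weight,strategy_effect_weight Non-negative
#'   weights of the two latent-score terms.  Both default to 1 (insert
#'   dominance comes from the geometry: long targeted inserts versus
#'   short strategy remnants); values other than 1 are experimental
#'   dials that void the exact-separability guarantee.
#' @param decision_threshold `NULL` for the generator's margin centre
#'   (0), `"median"` for the empirical median of the latent scores, or a
#'   number.
#' @param class_margin Half-width of the empty latent margin around the
#'   threshold (default 1.5, in units of summed normalized
#'   hydrophobicity).
#' @param band_width Width of each latent band (default 6).
#' @param label_noise Base label-flip probability, in `[0, 0.5)`.
#' @param strategy_noise_mult Per-strategy noise multipliers; default
#'   `c(1, ..., 1, 3)`.
#' @param flip_strategy Optional strategy index whose labels are
#'   additionally flipped with probability `flip_prob` (adversarial
#'   stratum for misclassification analyses).
#' @param flip_prob Flip probability for `flip_strategy` (default 1).
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_inserts = 71L, n_strategies = 8L,
                             insert_length = c(15L, 25L),
                             flank_n = 30L, flank_c = 25L,
                             core_length = 12L,
                             true_scale = NULL,
                             insert_effect_weight = 1,
                             strategy_effect_weight = 1,
                             decision_threshold = NULL,
                             class_margin = 1.5, band_width = 6,
                             label_noise = 0,
                             strategy_noise_mult = NULL,
                             flip_strategy = NULL, flip_prob = 1,
                             seed = 1L) {
  n_inserts <- as.integer(n_inserts); n_strategies <- as.integer(n_strategies)
  if (n_inserts < 2L || n_strategies < 1L)
    stopf("grid must have >= 2 inserts and >= 1 strategy")
  if (insert_effect_weight < 0 || strategy_effect_weight < 0)
    stopf("effect weights must be non-negative")
  if (insert_effect_weight == 0)
    stopf("insert_effect_weight must be positive (labels are insert-driven)")
  if (label_noise < 0 || label_noise >= 0.5)
    stopf("label_noise must lie in [0, 0.5)")
  if (is.null(strategy_noise_mult)) {
    strategy_noise_mult <- rep(1, n_strategies)
    if (n_strategies >= 2L) strategy_noise_mult[n_strategies] <- 3
  }
  if (length(strategy_noise_mult) != n_strategies)
    stopf("strategy_noise_mult needs one entry per strategy")
  if (any(label_noise * strategy_noise_mult >= 0.5))
    stopf("label_noise * strategy_noise_mult must stay below 0.5")
  if (!is.null(flip_strategy) &&
      (flip_strategy < 1L || flip_strategy > n_strategies))
    stopf("flip_strategy out of range")
  if (class_margin <= 0 || band_width <= 0)
    stopf("class_margin and band_width must be positive")
  structure(list(n_inserts = n_inserts, n_strategies = n_strategies,
                 insert_length = as.integer(insert_length),
                 flank_n = as.integer(flank_n), flank_c = as.integer(flank_c),
                 core_length = as.integer(core_length),
                 true_scale = true_scale,
                 insert_effect_weight = insert_effect_weight,
                 strategy_effect_weight = strategy_effect_weight,
                 decision_threshold = decision_threshold,
                 class_margin = class_margin, band_width = band_width,
                 label_noise = label_noise,
                 strategy_noise_mult = strategy_noise_mult,
                 flip_strategy = flip_strategy, flip_prob = flip_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Build a random sequence of length len whose summed value under v is
# within tol of target, by greedy single-residue swaps.
greedy_target_sequence <- function(len, target, v, tol = 0.3) {
  codes <- names(v)
  seq_codes <- sample(codes, len, replace = TRUE)
  u <- sum(v[seq_codes])
  tries <- 0L
  while (abs(u - target) > tol && tries < 200L * len) {
    tries <- tries + 1L
    pos <- sample.int(len, 1L)
    old <- v[[seq_codes[pos]]]
    cand <- target - (u - old)             # ideal replacement value
    new_code <- codes[which.min(abs(v - cand))]
    new_u <- u - old + v[[new_code]]
    if (abs(new_u - target) < abs(u - target)) {
      seq_codes[pos] <- new_code
      u <- new_u
    }
  }
  if (abs(u - target) > tol)
    stopf("could not construct an insert with target hydrophobicity %.2f at length %d",
          target, len)
  list(seq = paste(seq_codes, collapse = ""), u = u)
}

resolve_true_scale <- function(true_scale) {
  if (is.null(true_scale)) true_scale <- "KYTEDOOLITTLE"
  if (is.character(true_scale)) {
    lib <- example_scale_library(prepare = TRUE)
    if (!true_scale %in% lib$ids)
      stopf("unknown true_scale id '%s'", true_scale)
    return(lib[[true_scale]])
  }
  stopifnot(inherits(true_scale, "hydro_scale"))
  orient_scale(normalize_scale(true_scale))
}

#' Generate a synthetic labelled construct grid
#'
#' See [synthetic_config()] for the generative model.  The returned
#' ground truth records everything needed for parameter-recovery tests:
#' the generating scale, the threshold, per-insert latent contributions,
#' per-strategy core remnants and offsets, the full latent matrix, the
#' noise-free labels and the indices of noise-flipped records.
#'
#' @param cfg A [synthetic_config()].
#' @return List with elements `dataset` (a [construct_dataset()] with
#'   the full grid, labels, and flank trims as provenance) and `truth`.
#' @examples
#' sim <- generate_dataset(synthetic_config(n_inserts = 6, n_strategies = 2,
#'                                          seed = 7))
#' sim$dataset
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  scale <- resolve_true_scale(cfg$true_scale)
  v <- scale$values
  I <- cfg$n_inserts; S <- cfg$n_strategies

  flank_n <- paste(sample(AA_CODES, cfg$flank_n, replace = TRUE), collapse = "")
  flank_c <- paste(sample(AA_CODES, cfg$flank_c, replace = TRUE), collapse = "")
  core <- sample(AA_CODES, cfg$core_length, replace = TRUE)

  # strategy = insertion position + deletion length within the core
  strategies <- lapply(seq_len(S), function(s) {
    p <- sample.int(cfg$core_length + 1L, 1L) - 1L       # insert after p
    d_max <- min(4L, cfg$core_length - p)
    d <- sample.int(d_max + 1L, 1L) - 1L                 # residues deleted
    prefix <- paste(core[seq_len(p)], collapse = "")
    suffix <- if (p + d < cfg$core_length)
      paste(core[(p + d + 1L):cfg$core_length], collapse = "") else ""
    remnant <- paste0(prefix, suffix)
    c_s <- sum(v[split_residues(remnant)])
    if (!nzchar(remnant)) c_s <- 0
    list(prefix = prefix, suffix = suffix, remnant = remnant, offset = c_s)
  })
  c_s <- vapply(strategies, `[[`, numeric(1), "offset")
  wc <- cfg$strategy_effect_weight * c_s
  w_i <- cfg$insert_effect_weight
  m <- cfg$class_margin

  # latent bands for the per-insert contribution u = w_i * feature(insert):
  # all strategy-shifted latents of a "low" insert stay below -margin,
  # all of a "high" insert above +margin (threshold centre 0)
  tol <- 0.3
  lo_band <- c((-m - max(wc)) / w_i - cfg$band_width, (-m - max(wc)) / w_i)
  hi_band <- c((m - min(wc)) / w_i, (m - min(wc)) / w_i + cfg$band_width)

  n_low <- ceiling(I / 2)
  mode_low <- sample(rep(c(TRUE, FALSE), c(n_low, I - n_low)))
  v_absmax <- max(abs(v))
  inserts <- vector("list", I)
  u <- numeric(I)
  for (i in seq_len(I)) {
    band <- if (mode_low[i]) lo_band else hi_band
    target <- stats::runif(1L, band[1L] + tol, band[2L] - tol)
    lens <- seq(cfg$insert_length[1L], cfg$insert_length[2L])
    len <- lens[sample.int(length(lens), 1L)]
    len <- max(len, ceiling(abs(target) / (0.8 * v_absmax)))
    g <- greedy_target_sequence(len, target, v, tol)
    inserts[[i]] <- g$seq
    u[i] <- g$u
  }

  latent <- outer(w_i * u, wc, "+")                       # I x S
  thr <- cfg$decision_threshold
  thr <- if (is.null(thr)) 0
         else if (identical(thr, "median")) stats::median(latent)
         else as.numeric(thr)
  labels0 <- (latent < thr) * 1L

  p_flip <- matrix(rep(cfg$label_noise * cfg$strategy_noise_mult,
                       each = I), I, S)
  if (!is.null(cfg$flip_strategy))
    p_flip[, cfg$flip_strategy] <-
      1 - (1 - p_flip[, cfg$flip_strategy]) * (1 - cfg$flip_prob)
  flips <- matrix(stats::runif(I * S) < p_flip, I, S)
  labels <- ifelse(flips, 1L - labels0, labels0)

  grid <- expand.grid(insert_id = seq_len(I), strategy_id = seq_len(S))
  strategy_letters <- make.unique(rep(LETTERS, length.out = S), sep = "")
  records <- data.frame(
    construct_id = sprintf("i%02d_%s", grid$insert_id,
                           strategy_letters[grid$strategy_id]),
    insert_id = grid$insert_id,
    strategy_id = grid$strategy_id,
    sequence = vapply(seq_len(nrow(grid)), function(r) {
      s <- strategies[[grid$strategy_id[r]]]
      paste0(flank_n, s$prefix, inserts[[grid$insert_id[r]]], s$suffix,
             flank_c)
    }, character(1)),
    label = labels[cbind(grid$insert_id, grid$strategy_id)],
    stringsAsFactors = FALSE)

  ds <- construct_dataset(records, n_inserts = I, n_strategies = S,
                          trim_n = cfg$flank_n, trim_c = cfg$flank_c)
  truth <- list(true_scale = scale, threshold = thr,
                insert_feature = u, strategy_offset = c_s,
                strategy_remnant = vapply(strategies, `[[`, character(1),
                                          "remnant"),
                latent = latent, labels_clean = labels0,
                flipped = which(flips), mode_low = mode_low,
                flank_n = flank_n, flank_c = flank_c, config = cfg)
  list(dataset = ds, truth = truth)
}
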