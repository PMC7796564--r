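#' Configuration for the synthetic multi-block generator
#'
#' Describes a study in which compounds carry a four-class DILI label, each
#' of several cell-line expression blocks is measured for every compound at
#' several dose/time replicates, and a single molecular-descriptor block has
#' one row per compound.  Defaults emulate the structure of the kind of
#' DILI screen this package targets: 233 compounds with class frequencies
#' (39, 90, 50, 54)/233 (about 3.3:1 imbalance after aggregation), 13
#' expression blocks of which only the first five carry weak signal, the
#' first of those (the "MCF7 role") somewhat stronger, and one moderately
#' informative descriptor block.  Effect sizes are calibrated so that, at
#' these dimensions, a single informative expression block cross-validates
#' at AUC about 0.55-0.60, the descriptor block at about 0.64, and
#' integrated models at about 0.6-0.7 -- the weak-signal regime such
#' screens actually operate in.  Feature counts are scaled down to desk
#' size (1000 expression features, 300 descriptors); full-size studies are a
#' configuration away.
#'
#' @param n_compounds number of compounds.
#' @param class_probs probabilities over the four DILI classes
#'   (most, less, ambiguous, no); must sum to 1.
#' @param n_blocks number of expression blocks (cell lines).
#' @param p_expr features per expression block.
#' @param p_chem width of the descriptor block.
#' @param informative_blocks indices (1-based) of expression blocks carrying
#'   signal.
#' @param n_informative_per_block informative features per informative block
#'   (the shared set g0001..; shared identity across blocks makes
#'   transferability analyses meaningful).
#' @param effect_size standardized mean shift d of each informative
#'   expression feature between the binary super-classes (classes 1-3 vs 4).
#' @param lead_effect_multiplier multiplier applied to `effect_size` in the
#'   first informative block (the strongest cell line).
#' @param chem_informative number of informative descriptors.
#' @param chem_effect standardized shift d for informative descriptors.
#' @param replicate_doses dose labels measured for every compound.
#' @param replicate_times incubation times, a subset of c(6, 24, 48).
#' @param within_compound_rho correlation, in \[0, 1), of the replicate noise
#'   vectors of one compound (compound-level latent term shared across
#'   doses/times).
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 233L,
                         class_probs = c(39, 90, 50, 54) / 233,
                         n_blocks = 13L,
                         p_expr = 1000L,
                         p_chem = 300L,
                         informative_blocks = 1:5,
                         n_informative_per_block = 10L,
                         effect_size = 0.3,
                         lead_effect_multiplier = 4 / 3,
                         chem_informative = 20L,
                         chem_effect = 0.35,
                         replicate_doses = c(1, 10),
                         replicate_times = c(6, 24, 48),
                         within_compound_rho = 0.5,
                         seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              class_probs = class_probs,
              n_blocks = as.integer(n_blocks),
              p_expr = as.integer(p_expr), p_chem = as.integer(p_chem),
              informative_blocks = as.integer(informative_blocks),
              n_informative_per_block = as.integer(n_informative_per_block),
              effect_size = effect_size,
              lead_effect_multiplier = lead_effect_multiplier,
              chem_informative = as.integer(chem_informative),
              chem_effect = chem_effect,
              replicate_doses = replicate_doses,
              replicate_times = replicate_times,
              within_compound_rho = within_compound_rho,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_compounds < 1L) stop("n_compounds must be positive")
  if (length(cfg$class_probs) != 4L || any(cfg$class_probs < 0) ||
      abs(sum(cfg$class_probs) - 1) > 1e-9)
    stop("class_probs must be 4 nonnegative probabilities summing to 1")
  if (cfg$n_blocks < 1L || cfg$p_expr < 1L || cfg$p_chem < 1L)
    stop("dimensions must be positive")
  if (length(cfg$informative_blocks) &&
      (min(cfg$informative_blocks) < 1L ||
       max(cfg$informative_blocks) > cfg$n_blocks))
    stop("informative_blocks out of range")
  if (cfg$n_informative_per_block > cfg$p_expr)
    stop("n_informative_per_block exceeds p_expr")
  if (cfg$chem_informative > cfg$p_chem)
    stop("chem_informative exceeds p_chem")
  if (cfg$within_compound_rho < 0 || cfg$within_compound_rho >= 1)
    stop("within_compound_rho must be in [0, 1)")
  if (!all(cfg$replicate_times %in% c(6, 24, 48)))
    stop("replicate_times must be a subset of {6, 24, 48}")
  invisible(cfg)
}

#' Generate a synthetic multi-block DILI dataset
#'
#' Draws four-class labels from `class_probs`; informative features have a
#' class-conditional mean shift d between the binary super-classes (classes
#' 1-3 = DILI concern vs class 4 = no concern), all other features are
#' standard normal noise.  Replicate rows of one compound share a
#' compound-level latent vector: an observation is
#' mu + sqrt(rho) z_compound + sqrt(1 - rho) eps, so replicate noise vectors
#' correlate at rho while every feature stays marginally N(mu, 1).
#'
#' @param config a [synth_config].
#' @return object of class `synth_bundle`: list with `blocks` (named list of
#'   observation-table data.frames, one per cell line), `descriptors`
#'   (compound x descriptor matrix), `labels` (data.frame compound_id,
#'   dili_class), `ground_truth` (named list of truly informative feature ids
#'   per block, plus `$chem`), and `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  validate_synth_config(config)
  generate_bundle(config, null_effects = FALSE)
}

#' Generate a null dataset with correlated replicates
#'
#' All effect sizes are forced to zero, so labels are independent of every
#' feature, while replicate rows of one compound remain correlated at
#' `within_compound_rho`.  This isolates the replicate-leakage mechanism:
#' pooled cross-validation that splits a compound's replicates across folds
#' can look strongly predictive on such data even though no signal exists.
#'
#' @param config a [synth_config] with `within_compound_rho > 0` and at least
#'   2 dose/time replicates.
#' @return a `synth_bundle`, as [synth_generate()].
#' @export
synth_null_replicates <- function(config = synth_config()) {
  validate_synth_config(config)
  n_rep <- length(config$replicate_doses) * length(config$replicate_times)
  if (n_rep < 2L) stop("need at least 2 replicates per compound")
  if (config$within_compound_rho <= 0)
    stop("within_compound_rho must be > 0 for the null-replicate design")
  generate_bundle(config, null_effects = TRUE)
}

generate_bundle <- function(cfg, null_effects) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  compounds <- sprintf("cmp%04d", seq_len(n))
  classes <- sample(1:4, n, replace = TRUE, prob = cfg$class_probs)
  ybin <- classes != 4L
  gene_ids <- sprintf("g%04d", seq_len(cfg$p_expr))
  chem_ids <- sprintf("chem%04d", seq_len(cfg$p_chem))
  rho <- cfg$within_compound_rho
  reps <- expand.grid(dose = cfg$replicate_doses, time_h = cfg$replicate_times,
                      KEEP.OUT.ATTRS = FALSE)
  n_rep <- nrow(reps)

  blocks <- vector("list", cfg$n_blocks)
  names(blocks) <- sprintf("CL%02d", seq_len(cfg$n_blocks))
  ground_truth <- list()
  inf_ids <- gene_ids[seq_len(cfg$n_informative_per_block)]
  for (b in seq_len(cfg$n_blocks)) {
    d_b <- 0
    if (!null_effects && b %in% cfg$informative_blocks) {
      d_b <- cfg$effect_size
      if (b == cfg$informative_blocks[1L]) d_b <- d_b * cfg$lead_effect_multiplier
    }
    mu <- matrix(0, n, cfg$p_expr)
    if (d_b != 0)
      mu[ybin, seq_len(cfg$n_informative_per_block)] <- d_b
    Z <- matrix(stats::rnorm(n * cfg$p_expr), n, cfg$p_expr)
    rows <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      E <- matrix(stats::rnorm(n * cfg$p_expr), n, cfg$p_expr)
      Xr <- mu + sqrt(rho) * Z + sqrt(1 - rho) * E
      colnames(Xr) <- gene_ids
      rows[[r]] <- data.frame(compound_id = compounds,
                              dose = reps$dose[r], time_h = reps$time_h[r],
                              Xr, check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    obs <- obs[order(match(obs$compound_id, compounds)), , drop = FALSE]
    rownames(obs) <- NULL
    attr(obs, "block_id") <- names(blocks)[b]
    blocks[[b]] <- obs
    ground_truth[[names(blocks)[b]]] <-
      if (d_b != 0) inf_ids else character(0)
  }

  d_chem <- if (null_effects) 0 else cfg$chem_effect
  mu_c <- matrix(0, n, cfg$p_chem)
  if (d_chem != 0) mu_c[ybin, seq_len(cfg$chem_informative)] <- d_chem
  descriptors <- mu_c + matrix(stats::rnorm(n * cfg$p_chem), n, cfg$p_chem)
  dimnames(descriptors) <- list(compounds, chem_ids)
  ground_truth$chem <-
    if (d_chem != 0) chem_ids[seq_len(cfg$chem_informative)] else character(0)

  labels <- data.frame(compound_id = compounds, dili_class = classes,
                       stringsAsFactors = FALSE)
  structure(list(blocks = blocks, descriptors = descriptors, labels = labels,
                 ground_truth = ground_truth, config = cfg),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic multi-block bundle: %d compounds, %d expression block(s) x %d features,\n",
              cfg$n_compounds, cfg$n_blocks, cfg$p_expr))
  cat(sprintf("  %d descriptors, %d replicate(s)/compound, rho = %.2f, seed = %d\n",
              cfg$p_chem,
              length(cfg$replicate_doses) * length(cfg$replicate_times),
              cfg$within_compound_rho, cfg$seed))
  tab <- table(factor(x$labels$dili_class, levels = 1:4))
  cat(sprintf("  DILI classes (most/less/ambiguous/no): %s\n",
              paste(tab, collapse = "/")))
  invisible(x)
}
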