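#' Simulation configuration
#'
#' Parameters of the synthetic bead-array generator. The defaults emulate
#' the study design the benchmark targets: 384 analytes; 42 study samples
#' (12 controls, 18 MS cases, 12 NMO cases) distributed over 4 plates; and
#' 12 replicate measurements of a pooled reference serum, 3 per plate.
#'
#' Intensities are right-skewed on the raw scale (log-normal around a
#' per-analyte baseline) with a raw-scale coefficient of variation of about
#' `noise_cv` plus a small additive noise floor, so the raw-scale standard
#' deviation grows with the mean -- the heteroscedasticity that the mean-SD
#' evaluation criterion is designed to detect.
#'
#' @param n_analytes number of analytes (bead IDs). Default 384.
#' @param n_controls,n_case1,n_case2 group sizes (controls, MS, NMO).
#' @param n_ref_replicates replicate measurements of the reference pool.
#' @param n_plates number of plates; reference replicates are spread evenly.
#' @param baseline_log_mean_range range (natural-log MFI) from which
#'   per-analyte baseline log-means are drawn uniformly.
#' @param noise_cv multiplicative noise magnitude, as SD/mean on the raw
#'   scale.
#' @param noise_sd_add SD of the additive noise floor, raw MFI units.
#' @param plate_shift_sd SD (log scale) of per-plate shifts.
#' @param sample_effect_sd SD (log scale) of the latent per-sample effect;
#'   all replicates of the reference pool share a single draw.
#' @param frac_affected_analytes fraction of analytes shifted in cases.
#' @param effect_size_log2 absolute log2 shift of affected analytes in case
#'   samples; the sign is randomized per analyte.
#' @param frac_missing fraction of cells set missing.
#' @param frac_nonpositive fraction of cells overwritten with values <= 0
#'   (instrument exports contain such readouts; QC must mask them).
#' @param frac_low_beadcount fraction of wells given a bead count <= 35.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_analytes = 384L,
                       n_controls = 12L, n_case1 = 18L, n_case2 = 12L,
                       n_ref_replicates = 12L, n_plates = 4L,
                       baseline_log_mean_range = c(log(50), log(10000)),
                       noise_cv = 0.15, noise_sd_add = 5,
                       plate_shift_sd = 0.10, sample_effect_sd = 0.10,
                       frac_affected_analytes = 0.10, effect_size_log2 = 1,
                       frac_missing = 0.02, frac_nonpositive = 0.01,
                       frac_low_beadcount = 0.005, seed = 1L) {
  cfg <- list(n_analytes = as.integer(n_analytes),
              n_controls = as.integer(n_controls),
              n_case1 = as.integer(n_case1), n_case2 = as.integer(n_case2),
              n_ref_replicates = as.integer(n_ref_replicates),
              n_plates = as.integer(n_plates),
              baseline_log_mean_range = as.numeric(baseline_log_mean_range),
              noise_cv = noise_cv, noise_sd_add = noise_sd_add,
              plate_shift_sd = plate_shift_sd,
              sample_effect_sd = sample_effect_sd,
              frac_affected_analytes = frac_affected_analytes,
              effect_size_log2 = effect_size_log2,
              frac_missing = frac_missing,
              frac_nonpositive = frac_nonpositive,
              frac_low_beadcount = frac_low_beadcount,
              seed = as.integer(seed))
  counts <- c("n_analytes", "n_controls", "n_case1", "n_case2",
              "n_ref_replicates", "n_plates")
  if (any(unlist(cfg[counts]) < 1L))
    stop("all counts must be >= 1")
  fracs <- c("frac_affected_analytes", "frac_missing", "frac_nonpositive",
             "frac_low_beadcount")
  if (any(unlist(cfg[fracs]) < 0 | unlist(cfg[fracs]) > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$noise_cv <= 0) stop("noise_cv must be > 0")
  if (length(cfg$baseline_log_mean_range) != 2L ||
      diff(cfg$baseline_log_mean_range) < 0)
    stop("baseline_log_mean_range must be an increasing pair")
  if (cfg$frac_affected_analytes > 0 && cfg$effect_size_log2 != 0 &&
      (cfg$n_case1 < 1L || cfg$n_case2 < 1L || cfg$n_controls < 1L))
    stop("case effects requested but a group size is zero")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a bead-array assay dataset
#'
#' Draws a full synthetic MFI matrix with annotation and ground truth under
#' the noise model
#' \deqn{y = \exp(\mu_i + plate + sample + effect + N(0,\sigma_m)) + N(0,\sigma_a),}
#' where \eqn{\sigma_m = \sqrt{\log(1 + cv^2)}} so that the raw-scale CV of
#' the multiplicative part equals `noise_cv`. Affected analytes are shifted
#' by `effect_size_log2` (random sign per analyte, on the log2 scale) in
#' both case groups. Reference-pool replicates share one latent sample
#' effect and are laid out `n_ref_replicates / n_plates` per plate.
#' Finally a fraction of cells is overwritten with values from a small
#' zero/negative set, and a fraction is set missing.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_output` with elements `matrix`
#'   (an [assay_matrix()] with bead counts), `meta` (a [sample_meta()]
#'   table) and `truth` (per-analyte data.frame: baseline log-mean,
#'   affected flag, signed true log2 effect).
#' @examples
#' sim <- simulate_assay(sim_config(n_analytes = 20, seed = 7))
#' dim(sim$matrix)
#' table(sim$meta$group)
#' @export
simulate_assay <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    A <- cfg$n_analytes
    groups <- c(rep("reference_pool", cfg$n_ref_replicates),
                rep("control", cfg$n_controls),
                rep("case_MS", cfg$n_case1),
                rep("case_NMO", cfg$n_case2))
    ids <- c(sprintf("Ref_%02d", seq_len(cfg$n_ref_replicates)),
             sprintf("Ctrl_%02d", seq_len(cfg$n_controls)),
             sprintf("MS_%02d", seq_len(cfg$n_case1)),
             sprintf("NMO_%02d", seq_len(cfg$n_case2)))
    S <- length(ids)
    # reference replicates evenly over plates; study samples round-robin
    plate_ref <- rep(seq_len(cfg$n_plates),
                     length.out = cfg$n_ref_replicates)
    plate_ref <- sort(plate_ref)
    n_study <- S - cfg$n_ref_replicates
    plate_study <- rep(seq_len(cfg$n_plates), length.out = n_study)
    plate <- c(plate_ref, plate_study)
    replicate <- c(seq_len(cfg$n_ref_replicates), rep(NA_integer_, n_study))
    meta <- sample_meta(ids, groups, sprintf("plate_%d", plate), replicate)

    analytes <- sprintf("BeadID_%03d", seq_len(A))
    # per-analyte baseline log-means: truncated normal over the stated
    # range (bell-shaped across antigens, as pooled log-MFI distributions
    # of antigen panels typically are; a uniform would make the pooled
    # post-transform distribution flat, which no real panel shows)
    rng <- cfg$baseline_log_mean_range
    bl_mu <- mean(rng)
    bl_sd <- max(diff(rng) / 4, 1e-8)
    pr <- stats::pnorm(rng, bl_mu, bl_sd)
    baseline <- stats::qnorm(stats::runif(A, pr[1], pr[2]), bl_mu, bl_sd)
    n_aff <- round(cfg$frac_affected_analytes * A)
    affected <- rep(FALSE, A)
    if (n_aff > 0) affected[sample.int(A, n_aff)] <- TRUE
    eff_sign <- ifelse(stats::runif(A) < 0.5, -1, 1)
    effect_log2 <- ifelse(affected, eff_sign * cfg$effect_size_log2, 0)

    plate_shift <- stats::rnorm(cfg$n_plates, 0, cfg$plate_shift_sd)
    # one latent effect per biological sample; the pool is one sample
    samp_eff <- numeric(S)
    ref_eff <- stats::rnorm(1, 0, cfg$sample_effect_sd)
    samp_eff[groups == "reference_pool"] <- ref_eff
    n_bio <- sum(groups != "reference_pool")
    samp_eff[groups != "reference_pool"] <-
      stats::rnorm(n_bio, 0, cfg$sample_effect_sd)

    sigma_m <- sqrt(log(1 + cfg$noise_cv^2))
    is_case <- groups %in% c("case_MS", "case_NMO")
    mu <- outer(baseline, rep(1, S)) +
      outer(rep(1, A), plate_shift[plate] + samp_eff) +
      outer(effect_log2 * log(2), as.numeric(is_case))
    vals <- exp(mu + matrix(stats::rnorm(A * S, 0, sigma_m), A, S))
    if (cfg$noise_sd_add > 0)
      vals <- vals + matrix(stats::rnorm(A * S, 0, cfg$noise_sd_add), A, S)
    dimnames(vals) <- list(analytes, ids)

    n_cells <- A * S
    n_np <- round(cfg$frac_nonpositive * n_cells)
    if (n_np > 0) {
      idx <- sample.int(n_cells, n_np)
      vals[idx] <- sample(c(0, 0, -0.5, -1, -2), n_np, replace = TRUE)
    }
    n_miss <- round(cfg$frac_missing * n_cells)
    if (n_miss > 0) vals[sample.int(n_cells, n_miss)] <- NA_real_

    beads <- matrix(40L + stats::rpois(n_cells, 60), A, S,
                    dimnames = dimnames(vals))
    n_low <- round(cfg$frac_low_beadcount * n_cells)
    if (n_low > 0) {
      idx <- sample.int(n_cells, n_low)
      beads[idx] <- sample(0:35, n_low, replace = TRUE)
    }

    truth <- data.frame(analyte_id = analytes,
                        baseline_log_mean = baseline,
                        affected = affected,
                        effect_log2 = effect_log2,
                        stringsAsFactors = FALSE)
    structure(list(matrix = assay_matrix(vals, bead_counts = beads),
                   meta = meta, truth = truth, config = cfg),
              class = "sim_output")
  })
}

#' Tiny deterministic fixture
#'
#' A hand-written 10 analytes x 8 samples dataset used in unit tests and
#' examples. It is byte-identical on every call and exercises the QC edge
#' cases on purpose: analyte `A09` is missing in 3 of 8 samples (37.5 % >
#' 19 %, so the analyte filter drops it), analyte `A10` carries a zero and
#' a negative readout, and two wells have bead counts below the >35
#' threshold.
#'
#' @return list of class `sim_output` (without a `truth` table).
#' @export
toy_fixture <- function() {
  ids <- c("Ref_01", "Ref_02", "Ref_03",
           "Ctrl_01", "Ctrl_02", "MS_01", "MS_02", "NMO_01")
  groups <- c(rep("reference_pool", 3), "control", "control",
              "case_MS", "case_MS", "case_NMO")
  plate <- c("plate_1", "plate_1", "plate_2",
             "plate_1", "plate_2", "plate_1", "plate_2", "plate_1")
  meta <- sample_meta(ids, groups, plate,
                      c(1L, 2L, 3L, rep(NA_integer_, 5)))
  vals <- matrix(c(
    100, 105,  98, 120, 115, 300, 280, 110,
     50,  52,  49,  60,  55,  58,  61,  57,
    800, 820, 790, 700, 750, 760, 710, 720,
     20,  22,  19,  25,  24,  21,  23,  26,
    400, 410, 395, 500, 480, 150, 160, 470,
     75,  80,  78,  90,  85,  88,  92,  83,
    150, 148, 152, 160, 155, 158, 149, 151,
    600, 610, 605, 620, 615, 590, 595, 612,
     NA,  33,  NA,  40,  NA,  42,  38,  41,
      0,  45,  44,  -2,  46,  43,  47,  48),
    nrow = 10, byrow = TRUE,
    dimnames = list(sprintf("A%02d", 1:10), ids))
  beads <- matrix(80L, 10, 8, dimnames = dimnames(vals))
  beads["A02", "Ctrl_01"] <- 30L   # below the >35 criterion
  beads["A07", "Ref_02"] <- 35L    # boundary: masked (strict >)
  beads["A03", "MS_01"] <- 36L     # boundary: retained
  structure(list(matrix = assay_matrix(vals, bead_counts = beads),
                 meta = meta, truth = NULL, config = NULL),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output\n")
  print(x$matrix)
  cat("  groups:", paste(sprintf("%s=%d", levels(x$meta$group),
                                 table(x$meta$group)), collapse = ", "), "\n")
  invisible(x)
}
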