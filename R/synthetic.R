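# Synthetic gait/WOMAC cohort generator.
#
# One latent severity scalar s in [0, 1] per subject drives everything:
#
#   * WOMAC: total = clip(round(96 * s + eps), 0, 96), eps ~ N(0, womac_noise_sd),
#     decomposed into 24 items by multinomial allocation (items capped at 4,
#     totals re-derived from items so records are internally consistent).
#     Group latent distributions are truncated normals on [0, 1] whose
#     post-truncation means reproduce the published group means (18.9 / 48.5 /
#     71.7 for mild / moderate / severe) and whose spreads, combined with the
#     WOMAC noise, approximate the published group SDs (11.9 / 6.8 / 10.3).
#   * Gait: each waveform parameter p has a baseline template (low-order
#     Fourier shapes fitted by eye to canonical gait curves) and an additive
#     severity effect profile. A subject's waveform is
#       template + u_p * profile_p + wiggle,
#     with channel u_p = effect_scale * (s - 0.5) + z_p, z_p ~ N(0,
#     gait_noise_sd * noise_scale) the subject's parameter-specific deviation,
#     and a small independent smooth Fourier wiggle. Routing subject noise
#     through the same profile as the group effect gives every
#     profile-sensitive feature approximately the same standardized group
#     separation, and leaves profile-insensitive features null -- a clean,
#     known operating point for selection-recovery tests. Within-group
#     variability is deliberately smaller than clinical gait data.
#
# Effect directions follow the published severity contrasts (knee varus level
# and stance area increase with severity; knee flexion amplitude, hip
# rotation-moment SD, ankle push-off power and walking speed decrease; initial
# double support increases; ...).

GW_WOMAC_GROUP_MEANS <- c(mild = 18.9, moderate = 48.5, severe = 71.7)
GW_WOMAC_GROUP_SDS   <- c(mild = 11.9, moderate = 6.8,  severe = 10.3)

#' Configuration of a synthetic cohort
#'
#' @param group_sizes Integer vector `(n_mild, n_moderate, n_severe)`,
#'   default `c(140, 182, 53)`.
#' @param seed Integer seed; every draw of the generator flows from it.
#' @param effect_scale Multiplier on the gait group-effect profiles (0 gives a
#'   null cohort whose waveforms are exchangeable across severity groups).
#' @param noise_scale Multiplier on the within-group gait channel noise.
#' @param womac_noise_sd SD (WOMAC points) of the noise separating the WOMAC
#'   total from the latent severity; must stay below the smallest group SD.
#' @param gait_noise_sd SD of the per-parameter subject deviation on the
#'   latent channel (latent units).
#' @param wiggle_scale Multiplier on the small smooth waveform wiggle.
#' @param planted_min_d Minimum pairwise standardized group difference
#'   (Cohen's d) for a feature to count as planted truth. The default 0.35
#'   sits at the power floor of the pairwise t-test at alpha = 3e-5 with the
#'   default group sizes (below it the procedure has essentially no power),
#'   so the planted set is exactly the features the generator moves enough
#'   for the procedure to plausibly find.
#' @param toe_off_pct Stance/swing boundary used for all subjects.
#' @param womac_group_means,womac_group_sds Target group means/SDs of the
#'   WOMAC total.
#' @param templates Per-parameter waveform templates and severity-effect
#'   profiles (default [gait_templates()]); zeroing a parameter's `profile`
#'   removes its planted effect.
#' @param spatiotemporal Scalar-characteristic templates: data.frame with
#'   `parameter`, `base`, `effect`, `noise_sd`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(140L, 182L, 53L),
                          seed = 1L,
                          effect_scale = 1,
                          noise_scale = 1,
                          womac_noise_sd = 5,
                          gait_noise_sd = 0.04,
                          wiggle_scale = 1,
                          planted_min_d = 0.35,
                          toe_off_pct = 60,
                          womac_group_means = GW_WOMAC_GROUP_MEANS,
                          womac_group_sds = GW_WOMAC_GROUP_SDS,
                          templates = gait_templates(),
                          spatiotemporal = spatiotemporal_templates()) {
  if (length(group_sizes) != 3L || any(group_sizes < 2))
    gw_validation_error("`group_sizes` must be three sizes, each >= 2")
  if (effect_scale < 0)
    gw_validation_error("`effect_scale` must be >= 0")
  if (womac_noise_sd < 0 || noise_scale < 0 || gait_noise_sd < 0)
    gw_validation_error("noise parameters must be >= 0")
  structure(list(group_sizes = as.integer(group_sizes),
                 seed = as.integer(seed),
                 effect_scale = effect_scale,
                 noise_scale = noise_scale,
                 womac_noise_sd = womac_noise_sd,
                 gait_noise_sd = gait_noise_sd,
                 wiggle_scale = wiggle_scale,
                 planted_min_d = planted_min_d,
                 toe_off_pct = toe_off_pct,
                 womac_group_means = womac_group_means,
                 womac_group_sds = womac_group_sds,
                 templates = templates,
                 spatiotemporal = spatiotemporal),
            class = "cohort_config")
}

# Truncated-normal moments on [a, b] (closed form).
tn_moments <- function(mu, sigma, a = 0, b = 1) {
  alpha <- (a - mu) / sigma; beta <- (b - mu) / sigma
  Z <- pnorm(beta) - pnorm(alpha)
  dphi <- dnorm(alpha) - dnorm(beta)
  m <- mu + sigma * dphi / Z
  v <- sigma^2 * (1 + (alpha * dnorm(alpha) - beta * dnorm(beta)) / Z -
                    (dphi / Z)^2)
  c(mean = m, var = v)
}

rtruncnorm01 <- function(n, mu, sigma) {
  pa <- pnorm((0 - mu) / sigma); pb <- pnorm((1 - mu) / sigma)
  qnorm(pa + runif(n) * (pb - pa)) * sigma + mu
}

# Latent group parameters (on the s in [0,1] scale): pre-truncation mean is
# solved so the post-truncation mean hits the target; the latent SD carries
# the part of the group variance not explained by WOMAC noise.
latent_group_params <- function(config) {
  out <- lapply(seq_len(3), function(g) {
    m_target <- config$womac_group_means[g] / 96
    sd_total <- config$womac_group_sds[g]
    lat_sd <- sqrt(max(sd_total^2 - config$womac_noise_sd^2,
                       (0.3 * sd_total)^2)) / 96
    f <- function(mu) tn_moments(mu, lat_sd)[["mean"]] - m_target
    mu <- uniroot(f, m_target + c(-6, 6) * lat_sd, tol = 1e-10,
                  extendInt = "yes")$root
    c(mu = mu, sigma = lat_sd)
  })
  names(out) <- severity_levels()
  out
}

#' Waveform templates and severity-effect profiles
#'
#' Baseline gait-cycle shapes and additive severity profiles for the twelve
#' registered parameters, on the 101-point cycle axis. Profiles encode the
#' direction (and approximate magnitude) of the published severity contrasts.
#'
#' @return Named list: per parameter a list with `template` and `profile`
#'   (numeric vectors, length 101) and `wiggle_sd` (SD of the smooth
#'   subject-specific wiggle).
#' @export
gait_templates <- function() {
  t <- GW_CYCLE_AXIS / 100
  tpl <- list()
  tpl$hip_rotation_moment <- local({
    tem <- 4.0 * sin(2 * pi * t) + 1.5 * sin(4 * pi * t + 1)
    list(template = tem, profile = -0.22 * tem)
  })
  tpl$hip_flexion_angle <- local({
    tem <- 5 + 25 * cos(2 * pi * t + 0.3)
    list(template = tem,
         profile = 1.2 * sin(4 * pi * t) + 0.8 * sin(6 * pi * t) - 1.5)
  })
  tpl$hip_adduction_angle <- local({
    tem <- 2 * sin(2 * pi * t) + 1.5 * sin(4 * pi * t) - 1.16
    list(template = tem,
         profile = -0.08 * (1 + sin(2 * pi * t)) + 0.45 * (tem - mean(tem)))
  })
  tpl$hip_power <- local({
    tem <- 0.8 + 2.2 * sin(2 * pi * t - 0.6) + 1.4 * sin(4 * pi * t + 1.1) +
      0.6 * sin(6 * pi * t)
    list(template = tem,
         profile = -0.30 * (tem - mean(tem)) - 0.35 * sin(6 * pi * t + 0.5))
  })
  tpl$pelvic_obliquity_angle <- local({
    tem <- 1.2 + 2.6 * cos(2 * pi * t - 2.5)
    list(template = tem, profile = -0.6 * cos(2 * pi * t - 2.5) + 0.15)
  })
  tpl$knee_extension_moment <- local({
    tem <- 1.5 * sin(2 * pi * t) + 1.0 * sin(4 * pi * t + 0.8) +
      0.6 * sin(6 * pi * t)
    list(template = tem, profile = -0.25 * tem - 0.3 * sin(4 * pi * t + 2))
  })
  tpl$knee_flexion_angle <- local({
    tem <- 25 - 19 * cos(2 * pi * t) - 10 * cos(4 * pi * t - 0.9)
    list(template = tem, profile = -0.30 * (tem - 25))
  })
  tpl$knee_power <- local({
    tem <- -2 + 3 * sin(2 * pi * t - 0.8) + 2.5 * sin(4 * pi * t + 2.8)
    list(template = tem, profile = -0.30 * (tem + 2))
  })
  tpl$knee_varus_angle <- local({
    tem <- 5.4 + 1.8 * sin(2 * pi * t + 0.6) + 0.8 * sin(4 * pi * t)
    list(template = tem,
         profile = 6.9 + 2.4 * sin(2 * pi * t + 0.6) + 1.2 * sin(6 * pi * t + 1))
  })
  tpl$ankle_plantarflexion_moment <- local({
    tem <- 0.5 - 0.6 * cos(2 * pi * t) - 0.35 * cos(4 * pi * t) +
      0.25 * sin(6 * pi * t)
    list(template = tem,
         profile = 0.35 + 0.35 * cos(2 * pi * t) - 0.2 * sin(4 * pi * t))
  })
  tpl$ankle_power <- local({
    push <- exp(-((t - 0.52) / 0.045)^2)
    tem <- -0.5 + 0.4 * sin(2 * pi * t) + 5.8 * push -
      0.9 * exp(-((t - 0.10) / 0.06)^2)
    list(template = tem,
         profile = -1.3 * push + 0.4 * sin(6 * pi * t + 1) + 0.15)
  })
  tpl$foot_progression_angle <- local({
    tem <- -5 + 1.5 * sin(2 * pi * t) + 0.6 * sin(4 * pi * t + 0.4)
    list(template = tem, profile = 0.9 + 0.25 * sin(2 * pi * t))
  })
  for (p in names(tpl))
    tpl[[p]]$wiggle_sd <- 0.01 * stats::sd(tpl[[p]]$template)
  tpl
}

# base value, severity slope (per unit latent channel) and noise SD of the
# spatiotemporal scalars
spatiotemporal_templates <- function() {
  data.frame(
    parameter = spatiotemporal_parameters()$parameter,
    base  = c(80, 105, 110, 55, 9, 1.1, 0.55, 60, 40, 34.8, 15.3, 11, 8, 52, 1.1, 50),
    effect = c(-12, 0, 0, 0, 0, 0, 0, 0, 0, -3.5, 3.5, 0, 2.5, 0, 0, 0),
    noise_sd = c(0.8, 6, 9, 5, 1.5, 0.08, 0.05, 1.4, 1.4, 0.35, 0.35, 1.2,
                 0.3, 2, 0.09, 1.5),
    stringsAsFactors = FALSE)
}

womac_items_from_total <- function(total) {
  counts <- as.integer(rmultinom(1, total, rep(1, 24)))
  while (any(counts > 4L)) {
    excess <- sum(counts[counts > 4L] - 4L)
    counts[counts > 4L] <- 4L
    cap <- which(counts < 4L)
    take <- if (excess >= length(cap)) cap else sample(cap, excess)
    counts[take] <- counts[take] + 1L
  }
  counts
}

#' Generate a synthetic severity cohort
#'
#' Reproducible given the config seed. Subjects are generated per severity
#' group; their WOMAC records and gait waveforms both derive from the same
#' latent severity, so downstream severity classes (re-derived from totals)
#' agree with the generating group for the large majority of subjects.
#'
#' @param config A [cohort_config()].
#' @return A `gait_cohort` whose `meta` records the generating group and
#'   latent severity per subject.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(group_sizes = c(5, 5, 5), seed = 7))
#' cohort_size(cohort)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    gw_validation_error("`config` must be a cohort_config")
  set.seed(config$seed)
  sizes <- config$group_sizes
  n <- sum(sizes)
  group <- factor(rep(severity_levels(), times = sizes),
                  levels = severity_levels(), ordered = TRUE)
  lat <- latent_group_params(config)
  s <- numeric(n)
  for (g in seq_len(3)) {
    idx <- which(as.integer(group) == g)
    s[idx] <- rtruncnorm01(length(idx), lat[[g]][["mu"]], lat[[g]][["sigma"]])
  }
  total <- pmin(96L, pmax(0L, as.integer(round(
    96 * s + rnorm(n, 0, config$womac_noise_sd)))))
  items <- t(vapply(total, womac_items_from_total, integer(24)))
  subject_ids <- sprintf("S%04d", seq_len(n))
  womac <- data.frame(subject_id = subject_ids, items)
  names(womac) <- c("subject_id", sprintf("item_%02d", 1:24))

  tpl <- config$templates
  u_centred <- config$effect_scale * (s - 0.5)
  waveforms <- lapply(tpl, function(pp) {
    u <- u_centred + rnorm(n, 0, config$gait_noise_sd * config$noise_scale)
    tt <- GW_CYCLE_AXIS / 100
    basis <- cbind(sin(2 * pi * tt), cos(2 * pi * tt),
                   sin(4 * pi * tt), cos(4 * pi * tt),
                   sin(6 * pi * tt), cos(6 * pi * tt))
    coef_sd <- pp$wiggle_sd * config$wiggle_scale / sqrt(3)
    W <- basis %*% matrix(rnorm(6 * n, 0, coef_sd), 6, n)
    matrix(pp$template, 101, n) + outer(pp$profile, u) + W
  })

  spt <- config$spatiotemporal
  spatiotemporal <- as.data.frame(lapply(seq_len(nrow(spt)), function(i)
    spt$base[i] + spt$effect[i] * u_centred + rnorm(n, 0, spt$noise_sd[i])))
  names(spatiotemporal) <- spt$parameter

  meta <- data.frame(subject_id = subject_ids, group = group, latent = s,
                     stringsAsFactors = FALSE)
  gait_cohort(subject_ids, waveforms, spatiotemporal, womac,
              phase_map = default_phase_map(config$toe_off_pct), meta = meta)
}

#' Ground-truth planted features of a configuration
#'
#' Identifies, by config introspection, the features the generator actually
#' moves across severity groups: one reference cohort is simulated at the
#' config seed with group sizes scaled up by `ref_scale` (so the effect-size
#' estimates are stable), severity classes are re-derived from the WOMAC
#' totals, and a feature is planted truth when all three pairwise
#' standardized group differences (pooled-SD Cohen's d) reach
#' `config$planted_min_d`. With `effect_scale = 0` the list is empty.
#'
#' @param config A [cohort_config()].
#' @param registry Feature registry to introspect (default full grid).
#' @param ref_scale Multiplier on the group sizes of the reference simulation.
#' @return Character vector of feature ids.
#' @export
planted_truth <- function(config, registry = build_feature_registry("full"),
                          ref_scale = 5L) {
  ref <- config
  ref$group_sizes <- as.integer(config$group_sizes * ref_scale)
  cohort <- generate_cohort(ref)
  fm <- suppressMessages(drop_masked_features(extract_features(cohort, registry)))
  classes <- classify_scale_scores(cohort_womac_totals(cohort), "total")
  if (any(table(classes) < 2)) return(character(0))
  d <- pairwise_cohens_d(fm$values, classes)
  md <- apply(abs(d), 1, min)   # NA for zero-variance (unmoved) features
  colnames(fm$values)[!is.na(md) & md >= config$planted_min_d]
}

# p x 3 matrix of pairwise pooled-SD standardized mean differences
pairwise_cohens_d <- function(X, classes) {
  lev <- levels(classes)
  ns <- tabulate(classes, nbins = 3)
  ms <- vs <- matrix(0, ncol(X), 3)
  for (g in 1:3) {
    Xg <- X[classes == lev[g], , drop = FALSE]
    ms[, g] <- colMeans(Xg)
    vs[, g] <- apply(Xg, 2, var)
  }
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3))
  d <- sapply(seq_len(3), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    sp <- sqrt(((ns[i] - 1) * vs[, i] + (ns[j] - 1) * vs[, j]) /
                 (ns[i] + ns[j] - 2))
    (ms[, i] - ms[, j]) / sp
  })
  colnames(d) <- c("mild_moderate", "moderate_severe", "mild_severe")
  d
}

#' Analytic attainable hold-out correlation of a configuration
#'
#' The WOMAC total is latent severity (scaled to 0..96) plus independent noise
#' of SD `womac_noise_sd`; a model that recovered the latent exactly would
#' attain correlation `sqrt(V / (V + womac_noise_sd^2))` with the observed
#' totals, where `V` is the variance of the scaled latent over the evaluation
#' mixture. `V` is computed in closed form from the truncated-normal group
#' moments. Feature channels are designed to recover the latent almost
#' exactly, so this is the ceiling the fitted models should approach.
#'
#' @param config A [cohort_config()].
#' @param eval_sizes Group sizes of the evaluation cohort (defaults to the
#'   class-balanced down-sample of the config's groups to 231).
#' @return The attainable Pearson correlation (scalar in (0, 1)).
#' @export
attainable_r <- function(config,
                         eval_sizes = balanced_group_sizes(config$group_sizes, 231L)) {
  lat <- latent_group_params(config)
  w <- eval_sizes / sum(eval_sizes)
  mom <- vapply(lat, function(p) tn_moments(p[["mu"]], p[["sigma"]]), numeric(2))
  means <- 96 * mom["mean", ]
  vars <- 96^2 * mom["var", ]
  mbar <- sum(w * means)
  V <- sum(w * (vars + (means - mbar)^2))
  sqrt(V / (V + config$womac_noise_sd^2))
}
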