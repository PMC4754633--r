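#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' deterministic generators never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.round_counts <- function(mix, n) {
  # largest-remainder apportionment of n features over classes
  raw <- mix / sum(mix) * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}

.design_samples <- function(groups, zts, n_reps) {
  d <- expand.grid(replicate = seq_len(n_reps), zt = zts, group = groups,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("group", "zt", "replicate")]
  d$sample_id <- sprintf("%s_ZT%02d_r%d", d$group, as.integer(d$zt), d$replicate)
  d[, c("sample_id", "group", "zt", "replicate")]
}

#' Simulate a two-condition rhythmic time course with known truth
#'
#' Generates features following the cosine model
#' `y = m + A * cos(2*pi*(t - phi)/tau) + e`, `e ~ N(0, sigma^2)`, under the
#' around-the-clock design of the emulated study: two conditions, samples at
#' ZT 0/6/12/18 and five replicates per (condition, ZT) cell by default.
#' Each feature is planted into one of six differential-rhythmicity classes:
#'
#' 1. rhythmic in both conditions with identical period and acrophase;
#' 2. rhythmic in both, acrophase shifted by `phase_shift` hours in the
#'    second condition;
#' 3. rhythmic in both, period changed to `alt_period` in the second
#'    condition;
#' 4. rhythmic in the first condition only;
#' 5. rhythmic in the second condition only;
#' 6. arrhythmic in both (amplitude zero).
#'
#' Acrophases are drawn from the sampling grid so that noiseless parameters
#' are exactly recoverable at the scan's grid resolution.
#'
#' @param n_features number of features.
#' @param class_mix length-6 vector of class proportions (normalised
#'   internally); counts are apportioned by largest remainder.
#' @param zts sampling times in hours, strictly increasing, in `[0, 24)`.
#' @param n_reps replicates per (condition, ZT) cell.
#' @param groups two condition labels; the first plays the conventional
#'   colonised/reference role.
#' @param mesor baseline abundance `m` (implicit log2 scale).
#' @param amp_range range from which rhythmic amplitudes are drawn uniformly.
#' @param sigma Gaussian noise standard deviation.
#' @param phase_shift class-2 acrophase shift in hours.
#' @param period base period in hours.
#' @param alt_period class-3 period in the second condition, hours; must
#'   differ from `period` whenever class 3 has positive mass.
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @return list with elements `tcm` (a [time_course()]) and `truth`, a
#'   data.frame with one row per feature giving its class and per-condition
#'   mesor, amplitude, acrophase, period and noise sd.
#' @export
sim_rhythmic <- function(n_features = 200,
                         class_mix = rep(1 / 6, 6),
                         zts = c(0, 6, 12, 18),
                         n_reps = 5,
                         groups = c("SPF", "GF"),
                         mesor = 10,
                         amp_range = c(0.5, 2),
                         sigma = 0.25,
                         phase_shift = 6,
                         period = 24,
                         alt_period = 12,
                         seed = 1) {
  stopifnot(length(class_mix) == 6, all(class_mix >= 0), sum(class_mix) > 0,
            length(groups) == 2, all(diff(zts) > 0), n_reps >= 1)
  if (class_mix[3] > 0 && isTRUE(all.equal(alt_period, period)))
    stop("class 3 requires alt_period different from the base period")
  counts <- .round_counts(class_mix, n_features)
  classes <- rep.int(1:6, counts)
  samples <- .design_samples(groups, zts, n_reps)

  with_seed(seed, {
    amp <- stats::runif(n_features, amp_range[1], amp_range[2])
    phase <- sample(zts, n_features, replace = TRUE)
    truth <- data.frame(
      feature  = sprintf("f%04d", seq_len(n_features)),
      class    = classes,
      mesor    = mesor,
      sigma    = sigma,
      amp_A    = ifelse(classes %in% c(1, 2, 3, 4), amp, 0),
      phase_A  = phase %% period,
      period_A = period,
      amp_B    = ifelse(classes %in% c(1, 2, 3, 5), amp, 0),
      phase_B  = NA_real_,
      period_B = period,
      stringsAsFactors = FALSE
    )
    truth$phase_B <- truth$phase_A
    truth$phase_B[classes == 2] <- (truth$phase_A[classes == 2] + phase_shift) %% period
    truth$period_B[classes == 3] <- alt_period
    truth$phase_B[classes == 3] <- truth$phase_A[classes == 3] %% alt_period

    t_h <- samples$zt
    is_b <- samples$group == groups[2]
    vals <- matrix(0, n_features, nrow(samples))
    for (i in seq_len(n_features)) {
      a <- ifelse(is_b, truth$amp_B[i], truth$amp_A[i])
      ph <- ifelse(is_b, truth$phase_B[i], truth$phase_A[i])
      tau <- ifelse(is_b, truth$period_B[i], truth$period_A[i])
      vals[i, ] <- mesor + a * cos(2 * pi * (t_h - ph) / tau)
    }
    if (sigma > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), sd = sigma),
                            nrow(vals), ncol(vals))
    dimnames(vals) <- list(truth$feature, samples$sample_id)
    list(tcm = time_course(vals, samples), truth = truth)
  })
}

#' Simulate a seed-gene network dataset with planted partners
#'
#' In the first condition a latent driver signal propagates to the seed
#' feature and to `n_partners` partner features with loading `beta`; in the
#' second condition the partners are regenerated as independent noise,
#' emulating loss of a co-expression network, while background features are
#' independent noise in both conditions.
#'
#' @param n_background number of independent background features.
#' @param n_partners number of planted partner features.
#' @param beta partner loading on the driver in condition 1.
#' @param sigma noise sd added to seed and partners.
#' @param n_samples_per_group samples per condition; ZT labels are assigned
#'   cyclically over `zts` to satisfy the design container.
#' @param groups two condition labels.
#' @param zts ZT labels to cycle over.
#' @param mesor additive baseline.
#' @param seed integer seed.
#' @return list with `tcm` and `truth` (seed id, partner ids, beta).
#' @export
sim_network <- function(n_background = 200,
                        n_partners = 50,
                        beta = 1,
                        sigma = 0.25,
                        n_samples_per_group = 20,
                        groups = c("SPF", "GF"),
                        zts = c(0, 6, 12, 18),
                        mesor = 10,
                        seed = 1) {
  stopifnot(n_partners >= 1, n_background >= 0, n_samples_per_group >= 4)
  zt <- rep(zts, length.out = n_samples_per_group)
  rep_id <- stats::ave(seq_along(zt), zt, FUN = seq_along)
  samples <- do.call(rbind, lapply(groups, function(g)
    data.frame(sample_id = sprintf("%s_ZT%02d_r%d", g, as.integer(zt), rep_id),
               group = g, zt = zt, replicate = rep_id,
               stringsAsFactors = FALSE)))
  feats <- c("seed_gene",
             sprintf("partner_%03d", seq_len(n_partners)),
             if (n_background > 0) sprintf("bg_%04d", seq_len(n_background)))
  with_seed(seed, {
    n <- n_samples_per_group
    vals <- matrix(NA_real_, length(feats), nrow(samples),
                   dimnames = list(feats, samples$sample_id))
    for (g in seq_along(groups)) {
      cols <- samples$group == groups[g]
      driver <- stats::rnorm(n)
      vals["seed_gene", cols] <- mesor + driver + sigma * stats::rnorm(n)
      for (j in seq_len(n_partners)) {
        id <- sprintf("partner_%03d", j)
        if (g == 1) {
          vals[id, cols] <- mesor + beta * driver + sigma * stats::rnorm(n)
        } else {
          vals[id, cols] <- mesor + sqrt(beta^2 + sigma^2) * stats::rnorm(n)
        }
      }
      if (n_background > 0) {
        bg <- sprintf("bg_%04d", seq_len(n_background))
        vals[bg, cols] <- mesor + stats::rnorm(n_background * n)
      }
    }
    truth <- list(seed = "seed_gene",
                  partners = sprintf("partner_%03d", seq_len(n_partners)),
                  beta = beta)
    list(tcm = time_course(vals, samples), truth = truth)
  })
}

#' Simulate a metabolite bucket table with planted discriminant buckets
#'
#' Emulates a one-condition NMR bucket table sampled at several ZT classes.
#' `n_discriminant` buckets receive a ZT-dependent cosine mean shift of peak
#' size `effect`; every bucket additionally receives a shared structured
#' confounder (a per-sample latent factor with random bucket loadings,
#' residualised against the ZT classes so it is exactly uncorrelated with the
#' class structure) of scale `confounder_scale`, which is what orthogonal
#' signal correction is meant to remove.
#'
#' @param n_buckets total buckets.
#' @param n_discriminant planted class-discriminant buckets
#'   (`<= n_buckets`).
#' @param effect peak mean shift, in units of the noise sd.
#' @param confounder_scale scale of the shared class-orthogonal confounder.
#' @param zts ZT classes.
#' @param n_reps replicates per ZT.
#' @param sigma residual noise sd.
#' @param group condition label recorded for the samples.
#' @param mesor additive baseline.
#' @param seed integer seed.
#' @return list with `tcm` (buckets as features) and `discriminant`, the
#'   planted bucket ids.
#' @export
sim_buckets <- function(n_buckets = 200,
                        n_discriminant = 20,
                        effect = 1.5,
                        confounder_scale = 1,
                        zts = c(0, 6, 12, 18),
                        n_reps = 5,
                        sigma = 1,
                        group = "SPF",
                        mesor = 10,
                        seed = 1) {
  stopifnot(n_discriminant <= n_buckets, n_discriminant >= 0, n_reps >= 2)
  samples <- .design_samples(group, zts, n_reps)
  with_seed(seed, {
    n <- nrow(samples)
    ids <- sprintf("bucket_%03d", seq_len(n_buckets))
    vals <- matrix(stats::rnorm(n_buckets * n, sd = sigma), n_buckets, n,
                   dimnames = list(ids, samples$sample_id)) + mesor
    if (n_discriminant > 0 && effect != 0) {
      ph <- sample(zts, n_discriminant, replace = TRUE)
      for (j in seq_len(n_discriminant))
        vals[j, ] <- vals[j, ] + effect * cos(2 * pi * (samples$zt - ph[j]) / 24)
    }
    if (confounder_scale > 0) {
      u <- stats::rnorm(n)
      u <- u - stats::ave(u, samples$zt)    # exactly class-orthogonal
      load <- stats::rnorm(n_buckets)
      vals <- vals + confounder_scale * outer(load, u)
    }
    list(tcm = time_course(vals, samples),
         discriminant = if (n_discriminant > 0) ids[seq_len(n_discriminant)]
                        else character(0))
  })
}
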