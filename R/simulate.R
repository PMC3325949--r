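# Synthetic cohort generator.
#
# Sampling model, per group with mean vector mu and SD vector s:
#   subject latent (layer-correlated):  L ~ exchangeable-MVN(0, R(rho_layers))
#   per-eye noise  (layer-correlated):  E_eye ~ exchangeable-MVN(0, R(rho_layers))
#   eye value = mu + s * (sqrt(rho_eyes) * L + sqrt(1 - rho_eyes) * E_eye)
# so each eye's marginal SD is the target SD, the same-layer between-eye
# correlation is rho_eyes, and the within-eye between-layer correlation is
# rho_layers. Exchangeable-MVN draws use the one-factor construction
# z = sqrt(rho) * g0 + sqrt(1 - rho) * g_i with a shared standard normal g0.

# n x d matrix of exchangeable-correlation standard normals.
.rmvn_exch <- function(n, d, rho) {
  g0 <- stats::rnorm(n)
  z <- matrix(stats::rnorm(n * d), n, d)
  sqrt(rho) * g0 + sqrt(1 - rho) * z
}

# Truncated-normal draws via resampling (never clipping: no point mass).
.rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("truncated normal resampling failed to converge; check parameters")
}

.clinical_ranges <- list(
  age = c(18, 100), duration = c(0.5, 600), followup = c(0, 600),
  hy = c(1, 5), updrs_on = c(0, 108), updrs_off = c(0, 108)
)

#' Simulate a synthetic OCT cohort
#'
#' Draws a five-group cohort whose per-group, per-field marginal
#' distributions match the generator parameters (published group means and
#' SEM-derived SDs under the defaults of [default_params()]). Subject-level
#' layer panels are multivariate normal with exchangeable between-layer
#' correlation `rho_layers`; each subject receives two eyes whose same-field
#' values correlate at `rho_eyes` while keeping the target marginal SD.
#' Panel values are truncated below at 1 (resampled, not clipped). Scan
#' quality is normal (`quality_db_mean`, `quality_db_sd`) truncated at
#' `quality_db_floor`. Clinical covariates are drawn independently of the
#' layers (normal, clamped to their valid ranges); sex is balanced
#' Bernoulli(0.5).
#'
#' The same `params` and `seed` always reproduce the identical cohort.
#'
#' @param params An `oct_generator_params` bundle, see [default_params()].
#' @param seed Integer seed governing all draws.
#' @return A validated `oct_cohort` with `n_subjects` rows per group in the
#'   subjects table and two eyes per subject.
#' @examples
#' coh <- simulate_cohort(default_params(), seed = 1)
#' table(coh$subjects$group)
#' @export
simulate_cohort <- function(params = default_params(), seed = 1L) {
  validate_params(params)
  if (length(seed) != 1 || is.na(seed) || seed != round(seed)) {
    stop("`seed` must be a single integer")
  }
  set.seed(as.integer(seed))

  subj_list <- list()
  eye_list <- list()
  for (g in names(params$groups)) {
    gp <- params$groups[[g]]
    n <- as.integer(gp$n_subjects)
    fields <- names(gp$mean)
    d <- length(fields)
    mu <- matrix(gp$mean, n, d, byrow = TRUE)
    s <- matrix(gp$sd, n, d, byrow = TRUE)

    re <- sqrt(params$rho_eyes)
    rn <- sqrt(1 - params$rho_eyes)
    # per-field floors: 1 um for thicknesses, 0.01 mm^3 for volumes
    floors <- matrix(
      ifelse(fields %in% panel_fields("volume"), 0.01, 1),
      n, d, byrow = TRUE
    )
    draw_subjects <- function(m, mu_m, s_m) {
      lat <- .rmvn_exch(m, d, params$rho_layers)
      list(
        left = mu_m + s_m * (re * lat + rn * .rmvn_exch(m, d,
                                                        params$rho_layers)),
        right = mu_m + s_m * (re * lat + rn * .rmvn_exch(m, d,
                                                         params$rho_layers))
      )
    }
    ey <- draw_subjects(n, mu, s)
    # resample whole subjects (latent + both eyes) violating the floor:
    # truncation of the joint distribution, no point mass, always converges
    for (i in 1:100) {
      bad <- which(rowSums(ey$left < floors) > 0 |
                     rowSums(ey$right < floors) > 0)
      if (!length(bad)) break
      redraw <- draw_subjects(length(bad), mu[bad, , drop = FALSE],
                              s[bad, , drop = FALSE])
      ey$left[bad, ] <- redraw$left
      ey$right[bad, ] <- redraw$right
    }
    if (length(bad)) {
      stop("panel resampling failed to clear the positivity floor; ",
           "check that means are well above zero relative to SDs")
    }
    left <- ey$left
    right <- ey$right
    colnames(left) <- colnames(right) <- fields

    ids <- sprintf("%s-%04d", g, seq_len(n))
    covs <- names(gp$clinical_mean)
    clin <- lapply(covs, function(cv) {
      x <- stats::rnorm(n, gp$clinical_mean[[cv]], gp$clinical_sd[[cv]])
      rng <- .clinical_ranges[[cv]]
      pmin(pmax(x, rng[1]), rng[2])
    })
    names(clin) <- covs
    getcov <- function(cv) if (cv %in% covs) clin[[cv]] else rep(NA_real_, n)

    subj_list[[g]] <- data.frame(
      subject_id = ids, group = g,
      age = getcov("age"),
      sex = sample(c("F", "M"), n, replace = TRUE),
      duration_months = getcov("duration"),
      followup_months = getcov("followup"),
      hy = getcov("hy"),
      updrs_on = getcov("updrs_on"),
      updrs_off = getcov("updrs_off"),
      visual_acuity = rep(1, n),
      stringsAsFactors = FALSE
    )

    q <- .rnorm_trunc(2L * n, params$quality_db_mean, params$quality_db_sd,
                      params$quality_db_floor)
    eye_meta <- data.frame(
      subject_id = rep(ids, 2L),
      side = rep(c("left", "right"), each = n),
      quality_db = q,
      stringsAsFactors = FALSE
    )
    panel <- rbind(left, right)
    # fill fields absent from this group's parameter vector with NA
    all_fields <- panel_fields()
    missing_fields <- setdiff(all_fields, fields)
    if (length(missing_fields)) {
      extra <- matrix(NA_real_, nrow(panel), length(missing_fields),
                      dimnames = list(NULL, missing_fields))
      panel <- cbind(panel, extra)
    }
    eye_list[[g]] <- cbind(eye_meta, as.data.frame(panel[, all_fields]))
  }

  subjects <- do.call(rbind, subj_list)
  eyes <- do.call(rbind, eye_list)
  rownames(subjects) <- rownames(eyes) <- NULL
  oct_cohort(subjects, eyes)
}
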