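# Published per-group OCT layer parameters and generator defaults.
#
# Means and SEMs are per group for every per-eye panel field; SDs are
# reconstructed as SEM * sqrt(n_subjects). Units: thickness fields in
# micrometres, macular volume fields in cubic millimetres.

#' Diagnostic group labels
#'
#' The five diagnostic groups: healthy controls, Parkinson's disease (PD),
#' multiple system atrophy (MSA), corticobasal syndrome (CBS), and
#' progressive supranuclear palsy (PSP).
#'
#' @return Character vector of the five group labels.
#' @export
group_labels <- function() c("Control", "PD", "MSA", "CBS", "PSP")

# Panel field names, grouped by measurement. Thickness in um unless noted.
.panel_thickness_fields <- c(
  "rnfl_mean", "rnfl_temporal", "rnfl_nasal", "rnfl_superior", "rnfl_inferior",
  "mt_total", "mt_central", "mt_peripheral",
  "mt_sup_peripheral", "mt_inf_peripheral", "mt_temp_peripheral",
  "mt_nasal_peripheral",
  "mt_sup_central", "mt_inf_central", "mt_temp_central", "mt_nasal_central",
  "rgc_ipl_nasal", "rgc_ipl_temporal",
  "inl_nasal", "inl_temporal",
  "opl_nasal", "opl_temporal",
  "onl_central"
)

.panel_volume_fields <- c(
  "mv_total", "mv_central", "mv_peripheral",
  "mv_sup_peripheral", "mv_inf_peripheral", "mv_temp_peripheral",
  "mv_nasal_peripheral",
  "mv_sup_central", "mv_inf_central", "mv_temp_central", "mv_nasal_central"
)

#' Layer panel field names
#'
#' All per-eye measurement fields: peripapillar RNFL (mean + 4 quadrants),
#' macular thickness and volume (total, central, peripheral + 8 sectors
#' each), RGC+IPL nasal/temporal, INL nasal/temporal, OPL nasal/temporal,
#' and the central ONL.
#'
#' @param what `"all"`, `"thickness"` (micrometres) or `"volume"`
#'   (cubic millimetres).
#' @return Character vector of field names.
#' @export
panel_fields <- function(what = c("all", "thickness", "volume")) {
  what <- match.arg(what)
  switch(what,
    all = c(.panel_thickness_fields, .panel_volume_fields),
    thickness = .panel_thickness_fields,
    volume = .panel_volume_fields
  )
}

# Per-group published group sizes.
.group_n <- c(Control = 35, PD = 40, MSA = 19, CBS = 10, PSP = 15)

# Per-eye panel means and SEMs by group. Row order = panel field; columns
# alternate mean/sem per group.
.layer_table <- local({
  txt <- "
field               ctl_m  ctl_s  pd_m   pd_s  msa_m  msa_s  psp_m  psp_s  cbs_m  cbs_s
rnfl_mean           99.13  1.587  97.33  1.61  93.79  1.92   93.8   2.84   94.17  3.32
rnfl_temporal       73.89  2.017  73.08  2.12  72.37  3.45   65.07  2.35   69.3   3.35
rnfl_nasal          71.99  2.341  73.49  2.40  68.18  2.23   75.4   4.58   72.5   3.84
rnfl_superior       121.6  2.782  117.2  2.70  115.9  3.7    116.5  4.77   123.2  4.87
rnfl_inferior       126.7  3.063  127.2  2.53  118.4  4.16   117.1  3.95   118.6  5.65
mt_total            317.6  2.691  317.4  2.66  308.2  4.13   302.3  5.02   311.5  3.30
mt_central          340.9  2.91   341.6  2.71  332.3  4.52   322.5  5.95   334.9  3.90
mt_peripheral       294.3  2.604  293.5  2.53  283.9  3.67   280    4.43   289.3  2.92
mt_sup_peripheral   296    2.706  296.3  2.43  284.6  3.80   280.3  4.61   294.5  3.54
mt_inf_peripheral   285.1  2.75   284.8  2.39  277.4  3.27   271    4.44   280.9  2.71
mt_temp_peripheral  283.6  2.383  283.8  2.29  273.7  3.53   273.6  5.24   276    2.46
mt_nasal_peripheral 312.1  2.941  310.1  2.58  299.4  4.06   291.5  3.86   306.5  4.19
mt_sup_central      343.1  2.737  343.6  2.85  334.7  5.00   326.6  7.24   337    4.22
mt_inf_central      340.7  3.119  342.3  2.90  330.5  4.26   320.8  6.32   334.8  3.42
mt_temp_central     333.8  2.989  334    2.68  327.2  4.93   318.5  7.83   326.5  3.16
mt_nasal_central    346.1  3.166  346.6  2.77  336.8  4.50   324    4.21   341.2  5.21
mv_total            1.01   0.01   1.01   0.01  0.99   0.01   0.95   0.02   1.00   0.01
mv_central          0.53   0.01   0.54   0.01  0.52   0.01   0.51   0.01   0.53   0.01
mv_peripheral       1.49   0.01   1.49   0.02  1.44   0.02   1.37   0.02   1.46   0.02
mv_sup_peripheral   1.52   0.01   1.51   0.01  1.45   0.02   1.35   0.05   1.49   0.03
mv_inf_peripheral   1.44   0.02   1.47   0.02  1.41   0.02   1.28   0.04   1.42   0.02
mv_temp_peripheral  1.43   0.02   1.42   0.02  1.39   0.02   1.34   0.04   1.39   0.02
mv_nasal_peripheral 1.58   0.02   1.55   0.02  1.54   0.03   1.47   0.04   1.56   0.03
mv_sup_central      0.53   0.01   0.53   0.01  0.53   0.01   0.51   0.01   0.53   0.01
mv_inf_central      0.53   0.01   0.54   0.01  0.52   0.01   0.53   0.04   0.57   0.04
mv_temp_central     0.52   0.01   0.53   0.01  0.51   0.01   0.50   0.01   0.51   0.01
mv_nasal_central    0.54   0.01   0.54   0.01  0.53   0.01   0.51   0.01   0.54   0.01
rgc_ipl_nasal       103.1  1.58   102.5  1.50  97.23  1.49   89.96  2.86   97.11  1.87
rgc_ipl_temporal    94.26  1.73   97.06  1.25  94.93  2.79   84.54  2.72   91.72  2.65
inl_nasal           44.63  0.89   48.19  1.04  44.1   1.483  40.43  1.40   46.28  3.62
inl_temporal        40.96  0.65   45.4   1.01  40.07  1.84   38.32  0.87   41     3.03
opl_nasal           36.14  1.59   35.21  0.84  34.53  1.56   43.5   3.25   41.17  4.60
opl_temporal        33.03  0.93   32.26  0.76  34.23  1.61   32.93  0.75   35.56  1.83
onl_central         105.1  1.71   105.8  2.46  104    2.29   93.92  2.17   116.3  4.49
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
})

# Clinical covariate means and SEMs (patient groups only). Controls are
# age- and sex-matched; disease covariates do not apply to them.
.clinical_table <- local({
  txt <- "
group  age_m  age_s  duration_m  duration_s  followup_m  followup_s  hy_m  hy_s  updrs_on_m  updrs_on_s  updrs_off_m  updrs_off_s
PD     61.2   2.0    8.1         0.8         30.8        3.0         2.5   0.2   18.4        1.3         35.7         3.3
MSA    63.2   1.7    4.3         0.1         23.2        3.7         3.2   0.2   36.4        3.8         33.4         4.4
CBS    63.2   2.4    2.7         1.5         18.4        3.7         2.3   0.3   27.2        4.5         35.0         5.7
PSP    71.3   1.5    4.3         3.3         16.7        3.6         2.8   0.3   29.2        3.5         36.0         5.6
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
})

.group_col_prefix <- c(
  Control = "ctl", PD = "pd", MSA = "msa", PSP = "psp", CBS = "cbs"
)

#' Default synthetic-cohort generator parameters
#'
#' Returns the full parameter bundle used by [simulate_cohort()]: for each
#' of the five diagnostic groups, the number of subjects, the per-field mean
#' vector and the per-field standard deviation reconstructed from the
#' published standard errors as `SEM * sqrt(n_subjects)`, plus clinical
#' covariate means/SDs for the patient groups. Controls carry an
#' age-matched age distribution (mean 64 y, SD 9 y) and no disease
#' covariates.
#'
#' Correlation structure defaults: exchangeable between-layer correlation
#' `rho_layers = 0.3`, between-eye correlation `rho_eyes = 0.8`. Scan
#' quality is drawn from a normal with mean 25 dB and SD 3 dB, truncated
#' below at `quality_db_floor = 20` dB so that default cohorts pass the
#' default quality filter.
#'
#' @param groups Character vector of groups to include (default all five);
#'   subsetting lets large single-group simulations avoid generating the
#'   others.
#' @return An object of class `oct_generator_params`: a list with element
#'   `groups` (named list of per-group parameter sets, each with
#'   `n_subjects`, `mean`, `sd`, `clinical_mean`, `clinical_sd`), and
#'   scalars `rho_layers`, `rho_eyes`, `quality_db_mean`, `quality_db_sd`,
#'   `quality_db_floor`.
#' @examples
#' p <- default_params()
#' p$groups$PSP$mean[["onl_central"]]  # 93.92
#' p$groups$PSP$sd[["onl_central"]]    # 2.17 * sqrt(15)
#' @export
default_params <- function(groups = group_labels()) {
  groups <- match.arg(groups, group_labels(), several.ok = TRUE)
  per_group <- lapply(groups, function(g) {
    pre <- .group_col_prefix[[g]]
    n <- .group_n[[g]]
    mu <- stats::setNames(
      .layer_table[[paste0(pre, "_m")]], .layer_table$field
    )
    sem <- stats::setNames(
      .layer_table[[paste0(pre, "_s")]], .layer_table$field
    )
    if (g == "Control") {
      cl_mean <- c(age = 64)
      cl_sd <- c(age = 9)
    } else {
      row <- .clinical_table[.clinical_table$group == g, ]
      covs <- c("age", "duration", "followup", "hy", "updrs_on", "updrs_off")
      cl_mean <- stats::setNames(
        as.numeric(row[paste0(covs, "_m")]), covs
      )
      cl_sd <- stats::setNames(
        as.numeric(row[paste0(covs, "_s")]) * sqrt(n), covs
      )
    }
    list(
      group = g, n_subjects = n,
      mean = mu, sd = sem * sqrt(n),
      sem = sem,
      clinical_mean = cl_mean, clinical_sd = cl_sd
    )
  })
  names(per_group) <- groups
  structure(
    list(
      groups = per_group,
      rho_layers = 0.3, rho_eyes = 0.8,
      quality_db_mean = 25, quality_db_sd = 3, quality_db_floor = 20
    ),
    class = "oct_generator_params"
  )
}

#' Validate generator parameters
#'
#' Checks group sizes, non-negative SDs, positive means, and correlation
#' parameters (`rho_layers` in \[0, 1), `rho_eyes` in \[0, 1\]; the implied
#' exchangeable correlation matrices are then positive semi-definite).
#'
#' @param params An `oct_generator_params` object.
#' @return `params`, invisibly; stops with a message on violation.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "oct_generator_params")) {
    stop("`params` must be an `oct_generator_params` object")
  }
  if (params$rho_layers < 0 || params$rho_layers >= 1) {
    stop("rho_layers must lie in [0, 1)")
  }
  if (params$rho_eyes < 0 || params$rho_eyes > 1) {
    stop("rho_eyes must lie in [0, 1]")
  }
  for (g in names(params$groups)) {
    gp <- params$groups[[g]]
    if (!is.numeric(gp$n_subjects) || gp$n_subjects < 1) {
      stop(sprintf("group %s: n_subjects must be a positive count", g))
    }
    if (any(gp$sd < 0)) stop(sprintf("group %s: negative SD", g))
    if (any(gp$mean <= 0)) stop(sprintf("group %s: non-positive mean", g))
  }
  invisible(params)
}

#' Write and read generator parameters as JSON
#'
#' Serializes the full parameter bundle (group sizes, mean/SD vectors,
#' clinical parameters, correlation and quality settings) to a JSON file
#' mirroring the `oct_generator_params` field names, and reads it back.
#'
#' @param params An `oct_generator_params` object.
#' @param path File path for the JSON document.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the validated `oct_generator_params`.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  doc <- unclass(params)
  # named vectors serialize as JSON objects (arrays would drop the names)
  doc$groups <- lapply(doc$groups, function(gp) {
    for (f in c("mean", "sd", "sem", "clinical_mean", "clinical_sd")) {
      gp[[f]] <- as.list(gp[[f]])
    }
    gp
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$groups <- lapply(raw$groups, function(gp) {
    gp$mean <- unlist(gp$mean)
    gp$sd <- unlist(gp$sd)
    gp$sem <- unlist(gp$sem)
    gp$clinical_mean <- unlist(gp$clinical_mean)
    gp$clinical_sd <- unlist(gp$clinical_sd)
    gp
  })
  validate_params(structure(raw, class = "oct_generator_params"))
}
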