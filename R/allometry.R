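#' Fit a linear allometry for one organ
#'
#' Ordinary least squares of organ dry weight (kg) on D^2 H (aboveground
#' and belowground woody parts) or on D^2 (leaves), with D and H in
#' metres. Trees flagged `leaf_excluded` are dropped from leaf fits.
#'
#' @param trees data.frame with columns `D`, `H`, the organ weight column
#'   (`wt_above`, `wt_below` or `wt_leaf`) and optionally `leaf_excluded`.
#' @param organ one of `"aboveground"`, `"belowground"`, `"leaf"`.
#' @param form predictor form; defaults to `"D2H_linear"` for woody organs
#'   and `"D2_linear"` for leaves.
#' @return An `allometric_fit` object with `slope` (kg per m3 or m2),
#'   `intercept` (kg), `n_trees` and `residual_sd`.
#' @examples
#' trees <- data.frame(D = c(1, sqrt(2)), H = 1,
#'                     wt_above = c(3, 5))
#' fit_allometry(trees, "aboveground")   # slope 2, intercept 1
#' @export
fit_allometry <- function(trees, organ = c("aboveground", "belowground",
                                           "leaf"),
                          form = NULL) {
  organ <- match.arg(organ)
  if (is.null(form)) form <- if (organ == "leaf") "D2_linear" else "D2H_linear"
  form <- match.arg(form, c("D2H_linear", "D2_linear"))
  wcol <- switch(organ, aboveground = "wt_above", belowground = "wt_below",
                 leaf = "wt_leaf")
  if (!wcol %in% names(trees)) stop("trees lacks column ", wcol)
  keep <- !is.na(trees[[wcol]])
  if (organ == "leaf" && "leaf_excluded" %in% names(trees))
    keep <- keep & !trees$leaf_excluded
  d <- trees[keep, ]
  if (nrow(d) < 2) stop("need at least 2 usable trees for ", organ)
  x <- if (form == "D2H_linear") d$D^2 * d$H else d$D^2
  if (stats::var(x) == 0) stop("zero predictor variance")
  fit <- stats::lm(d[[wcol]] ~ x)
  rsd <- if (nrow(d) > 2) {
    sqrt(sum(stats::residuals(fit)^2) / (nrow(d) - 2))
  } else NA_real_
  structure(list(organ = organ, form = form,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_trees = nrow(d),
                 residual_sd = rsd),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> %s: weight = %.4g * %s + %.4g  (n = %d, residual sd %.3g kg)\n",
              x$organ, x$slope,
              if (x$form == "D2H_linear") "D^2 H" else "D^2",
              x$intercept, x$n_trees, x$residual_sd))
  invisible(x)
}

#' Predict organ biomass from an allometric fit
#'
#' @param fit an `allometric_fit`.
#' @param D diameter at breast height, m.
#' @param H tree height, m (required for the D^2 H form).
#' @return biomass, kg; negative predictions are clipped to zero with a
#'   warning.
#' @export
predict_biomass <- function(fit, D, H = NULL) {
  stopifnot(inherits(fit, "allometric_fit"))
  if (any(D < 0)) stop("D must be nonnegative")
  x <- if (fit$form == "D2H_linear") {
    if (is.null(H)) stop("H is required for the D2H form")
    D^2 * H
  } else D^2
  y <- fit$slope * x + fit$intercept
  if (any(y < 0)) {
    warning("negative predicted biomass clipped to zero")
    y <- pmax(0, y)
  }
  y
}

#' Construct a per-organ carbon density series
#'
#' @param stand_age integer ages (years since planting).
#' @param AC,BC,LC aboveground woody, belowground woody, leaf carbon
#'   densities, kg-C/m2.
#' @param sd_AC,sd_BC,sd_LC optional standard deviations.
#' @return A `carbon_density_series` data.frame.
#' @export
carbon_density_series <- function(stand_age, AC, BC, LC,
                                  sd_AC = NA_real_, sd_BC = NA_real_,
                                  sd_LC = NA_real_) {
  n <- length(stand_age)
  stopifnot(length(AC) == n, length(BC) == n, length(LC) == n)
  if (any(c(AC, BC, LC) < 0, na.rm = TRUE))
    stop("carbon densities must be nonnegative")
  out <- data.frame(stand_age = stand_age, AC = AC, BC = BC, LC = LC,
                    sd_AC = rep(sd_AC, length.out = n),
                    sd_BC = rep(sd_BC, length.out = n),
                    sd_LC = rep(sd_LC, length.out = n))
  class(out) <- c("carbon_density_series", "data.frame")
  out
}

#' Reconstruct the stand carbon-density history from rings and quadrats
#'
#' For each stand age, the ring-derived diameters of the harvested model
#' trees give per-tree D^2 and D^2 H (heights from the `height_by_age`
#' table, linearly interpolated where missing). Ring-tree totals are
#' scaled to the stand with the survey-year ratio of quadrat totals to
#' ring-tree totals, stand biomass is `slope * total + intercept *
#' n_trees` per organ, carbon fractions convert dry weight to carbon, and
#' division by the summed quadrat area yields kg-C/m2. The sd columns
#' carry the tree-to-tree variability of the per-tree biomass (relative sd
#' across ring trees, scaled to the density).
#'
#' @param fits named list of `allometric_fit` objects: `above`, `below`
#'   (D^2 H form) and `leaf` (D^2 form).
#' @param rings data.frame `tree_id`, `age`, `ring_D` (m), nondecreasing
#'   within tree and ending at the harvest D.
#' @param height_by_age data.frame `age`, `H` (m).
#' @param quadrats data.frame `quadrat_id`, `area`, `tree_id`, `D`, `H`
#'   (one row per inventoried tree; `area` constant within quadrat).
#' @param carbon_fraction_wood carbon content of woody biomass (0.46).
#' @param carbon_fraction_leaf carbon content of leaf biomass (0.45).
#' @param d_unit unit of the `D` columns in `rings`/`quadrats`:
#'   `"m"` or `"cm"`.
#' @return A `carbon_density_series` with one row per stand age.
#' @export
reconstruct_carbon_series <- function(fits, rings, height_by_age, quadrats,
                                      carbon_fraction_wood = 0.46,
                                      carbon_fraction_leaf = 0.45,
                                      d_unit = c("m", "cm")) {
  d_unit <- match.arg(d_unit)
  for (nm in c("above", "below", "leaf"))
    if (!inherits(fits[[nm]], "allometric_fit"))
      stop("fits must contain allometric_fit objects 'above', 'below', 'leaf'")
  conv <- if (d_unit == "cm") 0.01 else 1
  rings$ring_D <- rings$ring_D * conv
  quadrats$D <- quadrats$D * conv
  ages <- sort(unique(rings$age))
  H_age <- if (nrow(height_by_age) == 1) {
    rep(height_by_age$H, length(ages))
  } else {
    stats::approx(height_by_age$age, height_by_age$H, xout = ages,
                  rule = 2)$y
  }
  area_total <- sum(tapply(quadrats$area, quadrats$quadrat_id, unique))
  n_quad_trees <- nrow(quadrats)
  if (n_quad_trees == 0 || area_total <= 0) stop("empty quadrats")
  sum_D2_quad <- sum(quadrats$D^2)
  sum_D2H_quad <- sum(quadrats$D^2 * quadrats$H)

  survey_age <- max(ages)
  ring_wide <- split(rings, rings$tree_id)
  per_age <- function(age) {
    vapply(ring_wide, function(tr) {
      i <- match(age, tr$age)
      if (is.na(i)) stop("ring series missing age ", age)
      tr$ring_D[i]
    }, numeric(1))
  }
  D_srv <- per_age(survey_age)
  H_srv <- H_age[match(survey_age, ages)]
  s_D2H <- sum_D2H_quad / sum(D_srv^2 * H_srv)
  s_D2 <- sum_D2_quad / sum(D_srv^2)

  res <- lapply(seq_along(ages), function(k) {
    D <- per_age(ages[k])
    H <- H_age[k]
    x_wood <- D^2 * H      # per ring tree
    x_leaf <- D^2
    dens <- function(fit, x, scale, cf) {
      tot <- fit$slope * scale * sum(x) + fit$intercept * n_quad_trees
      cf * max(0, tot) / area_total
    }
    cvof <- function(fit, x) {
      b <- pmax(0, fit$slope * x + fit$intercept)
      if (mean(b) > 0) stats::sd(b) / mean(b) else 0
    }
    ac <- dens(fits$above, x_wood, s_D2H, carbon_fraction_wood)
    bc <- dens(fits$below, x_wood, s_D2H, carbon_fraction_wood)
    lc <- dens(fits$leaf, x_leaf, s_D2, carbon_fraction_leaf)
    c(AC = ac, BC = bc, LC = lc,
      sd_AC = ac * cvof(fits$above, x_wood),
      sd_BC = bc * cvof(fits$below, x_wood),
      sd_LC = lc * cvof(fits$leaf, x_leaf))
  })
  m <- do.call(rbind, res)
  carbon_density_series(ages, m[, "AC"], m[, "BC"], m[, "LC"],
                        m[, "sd_AC"], m[, "sd_BC"], m[, "sd_LC"])
}

#' Mean belowground-to-aboveground carbon ratio
#'
#' Arithmetic mean over stand ages of BC_i / AC_i; used to pin the
#' coarse-root allocation ratio to the measured stand structure.
#'
#' @param series a `carbon_density_series`.
#' @return a single fraction.
#' @export
bc_ac_mean_ratio <- function(series) {
  if (any(series$AC <= 0)) stop("AC must be positive at every age")
  mean(series$BC / series$AC)
}

#' Read a harvest / quadrat / ring survey from CSV files
#'
#' Thin readers for the survey CSV dialects written by the synthetic
#' generator and used in the field workflow.
#'
#' @param harvest,rings,quadrats,height_by_age file paths.
#' @param d_unit unit of the D columns (`"m"` or `"cm"`).
#' @return list of data.frames as in [generate_survey()].
#' @export
read_survey_csv <- function(harvest, rings, quadrats, height_by_age,
                            d_unit = c("m", "cm")) {
  d_unit <- match.arg(d_unit)
  conv <- if (d_unit == "cm") 0.01 else 1
  h <- utils::read.csv(harvest, stringsAsFactors = FALSE)
  h$D <- h$D * conv
  if (!"leaf_excluded" %in% names(h)) h$leaf_excluded <- FALSE
  h$leaf_excluded <- as.logical(h$leaf_excluded)
  r <- utils::read.csv(rings, stringsAsFactors = FALSE)
  r$ring_D <- r$ring_D * conv
  q <- utils::read.csv(quadrats, stringsAsFactors = FALSE)
  q$D <- q$D * conv
  hb <- utils::read.csv(height_by_age, stringsAsFactors = FALSE)
  list(harvest = h, rings = r, quadrats = q, height_by_age = hb)
}

#' Load the bundled synthetic survey fixture
#'
#' A small survey (7 harvest trees, 4 quadrats of 16 trees, 11-year ring
#' series) constructed so that its least-squares allometries and
#' survey-year quadrat totals reproduce the published desk-scale constants
#' for an 11-year-old *Eucommia ulmoides* stand. It is a synthetic
#' stand-in, not field data.
#'
#' @return list of data.frames as in [generate_survey()] (D in metres).
#' @export
load_survey_fixture <- function() {
  p <- function(f) system.file("extdata", f, package = "afforcast",
                               mustWork = TRUE)
  read_survey_csv(p("synthetic_harvest.csv"), p("synthetic_rings.csv"),
                  p("synthetic_quadrats.csv"),
                  p("synthetic_height_by_age.csv"), d_unit = "m")
}
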