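#' Fit a standard curve (linear or four-parameter logistic)
#'
#' Calibration mapping analyte concentration to plate absorbance. The
#' linear model `A = intercept + slope * conc` is fit by least squares;
#' the four-parameter logistic (4PL) model
#' `A = d + (a - d) / (1 + (conc / c)^b)` — the usual sigmoid for
#' sandwich ELISAs — by Levenberg-Marquardt least squares. A blank
#' absorbance, if supplied, is averaged and subtracted before fitting.
#' A warning is issued when r-squared falls below 0.98.
#'
#' @param known_conc standard concentrations (>= 3, not all identical)
#' @param absorbance measured absorbances, same length
#' @param model `"linear"` or `"4pl"`
#' @param blank optional vector of blank-well absorbances
#' @return object of class `standard_curve`: `model`, `parameters`
#'   (named: `slope`, `intercept` or `a`, `b`, `c`, `d`), `r_squared`,
#'   `conc_range`, `abs_range`, `blank`
#' @examples
#' sc <- fit_standard(c(0, 1, 2, 4), 0.1 + 2 * c(0, 1, 2, 4))
#' sc$parameters # slope 2, intercept 0.1
#' @export
fit_standard <- function(known_conc, absorbance,
                         model = c("linear", "4pl"), blank = NULL) {
  model <- match.arg(model)
  stopifnot(length(known_conc) == length(absorbance))
  if (length(known_conc) < 3L) stop_param("at least 3 standards required")
  if (length(unique(known_conc)) < 2L)
    stop_param("standards must span distinct concentrations")
  blank_mean <- if (length(blank)) mean(blank) else 0
  y <- absorbance - blank_mean
  x <- known_conc
  if (model == "linear") {
    fit <- lm(y ~ x)
    pars <- c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
    fitted_y <- unname(stats::fitted(fit))
  } else {
    if (length(known_conc) < 4L) stop_param("4PL needs at least 4 standards")
    a0 <- y[which.min(x)]          # response at zero dose
    d0 <- y[which.max(x)]          # response at saturation
    c0 <- stats::median(x[x > 0])  # mid-dose
    fit <- minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / c)^b),
      start = list(a = a0, b = if (d0 >= a0) 1.5 else -1.5, c = c0, d = d0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    pars <- coef(fit)
    fitted_y <- predict(fit)
  }
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (r2 < 0.98)
    warning(sprintf("standard curve r-squared %.4f < 0.98", r2))
  structure(list(model = model, parameters = pars, r_squared = r2,
                 conc_range = range(x), abs_range = range(y),
                 blank = blank_mean),
            class = "standard_curve")
}

#' Predicted absorbance at given concentrations
#'
#' @param curve a [fit_standard()] result
#' @param conc concentrations
#' @return absorbances on the blank-subtracted scale
#' @export
abs_from_conc <- function(curve, conc) {
  p <- as.list(curve$parameters)
  if (curve$model == "linear") p$intercept + p$slope * conc
  else p$d + (p$a - p$d) / (1 + (conc / p$c)^p$b)
}

#' Invert a standard curve: concentration from absorbance
#'
#' Linear curves invert as `(A - intercept) / slope`; 4PL curves use the
#' closed-form inverse `c * ((a - d)/(A - d) - 1)^(1/b)`. Absorbances
#' outside the calibrated range are extrapolated with a warning and
#' flagged in the `extrapolated` attribute; absorbances outside the 4PL
#' asymptotes are not invertible and produce an error.
#'
#' @param curve a [fit_standard()] result
#' @param absorbance measured absorbances (raw scale; the curve's blank
#'   is subtracted internally)
#' @return concentrations, with logical attribute `extrapolated`
#' @export
conc_from_abs <- function(curve, absorbance) {
  y <- absorbance - curve$blank
  extrap <- y < curve$abs_range[1] - 1e-12 | y > curve$abs_range[2] + 1e-12
  if (any(extrap))
    warning(sum(extrap), " absorbance(s) outside the calibrated range; ",
            "extrapolating")
  p <- as.list(curve$parameters)
  if (curve$model == "linear") {
    if (p$slope == 0) stop_param("degenerate linear curve: zero slope")
    out <- (y - p$intercept) / p$slope
  } else {
    lo <- min(p$a, p$d); hi <- max(p$a, p$d)
    if (any(y <= lo | y >= hi))
      stop_param("absorbance outside the 4PL asymptotes (",
                 signif(lo, 4), ", ", signif(hi, 4), "): not invertible")
    out <- p$c * ((p$a - p$d) / (y - p$d) - 1)^(1 / p$b)
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Protein-normalized sample quantification
#'
#' Metabolite (or peptide) levels are reported as the ratio to total
#' protein to normalize for animal size, after undoing any dilution
#' (hemolymph is typically assayed at a 10-fold dilution).
#'
#' @param raw_conc concentration read off the standard curve
#' @param dilution_factor fold dilution applied before the assay (>= 1)
#' @param protein_conc protein concentration of the same sample (> 0)
#' @return list of class `sample_quant`: `raw_conc`, `dilution_factor`,
#'   `protein_conc`, `normalized` (= raw * dilution / protein)
#' @export
normalize_sample <- function(raw_conc, dilution_factor = 1, protein_conc) {
  dilution_factor <- check_number(dilution_factor, "dilution_factor", min = 1)
  protein_conc <- check_number(protein_conc, "protein_conc",
                               min = 0, strict_min = TRUE)
  structure(list(raw_conc = raw_conc, dilution_factor = dilution_factor,
                 protein_conc = protein_conc,
                 normalized = raw_conc * dilution_factor / protein_conc),
            class = "sample_quant")
}

#' Quantify ELISA samples against a peptide standard series
#'
#' Fits the standard curve (4PL by default, as appropriate for sandwich
#' assays) and inverts it at the sample absorbances. Samples outside the
#' standards' absorbance span are flagged as extrapolated.
#'
#' @param standard_conc,standard_abs the standard series
#' @param sample_abs sample absorbances (e.g. A450)
#' @param model `"4pl"` (default) or `"linear"`
#' @param dilution_factor fold dilution of the samples
#' @return data frame: `absorbance`, `conc`, `conc_undiluted`,
#'   `extrapolated`; the fitted curve in attribute `curve`
#' @export
elisa_quantify <- function(standard_conc, standard_abs, sample_abs,
                           model = c("4pl", "linear"), dilution_factor = 1) {
  model <- match.arg(model)
  curve <- fit_standard(standard_conc, standard_abs, model = model)
  conc <- conc_from_abs(curve, sample_abs)
  out <- data.frame(absorbance = sample_abs, conc = as.numeric(conc),
                    conc_undiluted = as.numeric(conc) * dilution_factor,
                    extrapolated = attr(conc, "extrapolated"))
  attr(out, "curve") <- curve
  out
}

#' Convert molar to mass concentration
#'
#' `mM x g/mol` gives `mg/L`, i.e. micrograms per milliliter: 5 mM
#' glucose (molar mass 180) is 900 ug/mL.
#'
#' @param conc_mM molar concentration in mM
#' @param molar_mass molar mass in g/mol
#' @return mass concentration in ug/mL
#' @export
molar_to_mass <- function(conc_mM, molar_mass) {
  check_number(molar_mass, "molar_mass", min = 0, strict_min = TRUE)
  conc_mM * molar_mass
}

#' Sugar percentage of a fold-change diet
#'
#' The feeding paradigm scales the base recipe's sucrose: the normal
#' diet contains 6% sucrose, so the 5x high-sugar diet contains 30%,
#' with other ingredients unchanged.
#'
#' @param fold sugar fold-change relative to the base diet
#' @param base_pct base-diet sucrose percentage (default 6)
#' @return sucrose percentage of the scaled diet
#' @examples
#' diet_sugar_pct(5) # 30
#' @export
diet_sugar_pct <- function(fold, base_pct = 6) {
  check_number(fold, "fold", min = 0)
  fold * base_pct
}

#' Simulate a plate-reader absorbance table
#'
#' Beer-Lambert linear response: `absorbance = intercept + slope * conc`
#' plus Gaussian noise. Standard wells span the sample concentration
#' range (from 0 to 1.25x the maximum sample concentration); blank wells
#' carry the intercept.
#'
#' @param concentrations true sample concentrations (non-empty)
#' @param slope absorbance per concentration unit (non-zero)
#' @param intercept blank absorbance
#' @param noise_sd absorbance noise SD
#' @param n_standards number of standard wells (>= 3)
#' @param n_blanks number of blank wells
#' @param seed integer seed
#' @return list with `plate` (data frame: `well`, `role`, `known_conc`,
#'   `absorbance`) and `truth` (`slope`, `intercept`,
#'   `sample_conc`)
#' @export
sim_plate <- function(concentrations, slope, intercept = 0.05,
                      noise_sd = 0, n_standards = 8, n_blanks = 2,
                      seed = 1) {
  if (length(concentrations) == 0L) stop_param("empty concentration list")
  if (!is.numeric(slope) || slope == 0) stop_param("slope must be non-zero")
  n_standards <- check_count(n_standards, "n_standards", min = 3L)
  std_conc <- seq(0, max(concentrations) * 1.25, length.out = n_standards)
  conc_all <- c(std_conc, concentrations, rep(0, n_blanks))
  role <- c(rep("standard", n_standards),
            rep("sample", length(concentrations)),
            rep("blank", n_blanks))
  local_seed(seed, {
    ab <- intercept + slope * conc_all
    if (noise_sd > 0) ab <- ab + rnorm(length(ab), 0, noise_sd)
    plate <- data.frame(
      well = sprintf("W%02d", seq_along(conc_all)), role = role,
      known_conc = ifelse(role == "standard", conc_all, NA_real_),
      absorbance = ab)
    list(plate = plate,
         truth = list(slope = slope, intercept = intercept,
                      sample_conc = concentrations))
  })
}
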