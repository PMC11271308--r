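#' Construct and validate a pupariation curve
#'
#' One genotype x diet x vial cumulative pupariation record. Fractions
#' are cumulative pupae over larvae seeded.
#'
#' @param obs_times observation times (h AEL), strictly increasing
#' @param cum_pupae cumulative pupae counts, non-decreasing
#' @param n_seeded larvae seeded into the vial
#' @param genotype,diet,vial identifying labels
#' @return an object of class `pup_curve` with fields `obs_times`,
#'   `cum_fraction`, `n_pupae_final`, `n_seeded` and the labels
#' @export
pup_curve <- function(obs_times, cum_pupae, n_seeded,
                      genotype = NA_character_, diet = NA_character_,
                      vial = NA) {
  if (length(obs_times) == 0L) stop_param("empty curve")
  if (length(obs_times) != length(cum_pupae))
    stop_param("obs_times and cum_pupae lengths differ")
  if (any(diff(obs_times) <= 0)) stop_param("obs_times must be strictly increasing")
  if (any(diff(cum_pupae) < 0)) stop_param("cum_pupae must be non-decreasing")
  n_seeded <- check_count(n_seeded, "n_seeded")
  if (any(cum_pupae > n_seeded)) stop_param("cum_pupae exceeds n_seeded")
  structure(list(
    genotype = genotype, diet = diet, vial = vial,
    obs_times = as.numeric(obs_times),
    cum_fraction = as.numeric(cum_pupae) / n_seeded,
    n_pupae_final = as.integer(cum_pupae[length(cum_pupae)]),
    n_seeded = n_seeded
  ), class = "pup_curve")
}

#' Time to 50% pupariation
#'
#' The P50 statistic: the time at which half of the vial's larvae have
#' pupariated, obtained by linear interpolation between the observations
#' flanking the 50% point. If an observation hits 0.5 exactly the
#' earliest such time is returned; if the curve never reaches 0.5 the
#' vial is flagged as arrested (`reached = FALSE`, `p50 = NA`). Vials
#' with fewer than three pupae are marked non-qualifying and are
#' excluded from replicate averaging downstream.
#'
#' @param curve a [pup_curve()]
#' @return an object of class `p50_result`: list with `p50` (hours, `NA`
#'   when arrested), `reached`, `n_pupae_final`, `qualifies`
#' @examples
#' cv <- pup_curve(c(96, 104), c(8, 12), 20)
#' p50_time(cv)$p50 # 100: 96 + (0.5 - 0.4)/(0.6 - 0.4) * 8
#' @export
p50_time <- function(curve) {
  if (!inherits(curve, "pup_curve"))
    curve <- do.call(pup_curve, curve)
  f <- curve$cum_fraction
  t <- curve$obs_times
  qualifies <- curve$n_pupae_final >= 3L
  if (max(f) < 0.5)
    return(structure(list(p50 = NA_real_, reached = FALSE,
                          n_pupae_final = curve$n_pupae_final,
                          qualifies = qualifies), class = "p50_result"))
  i_hit <- which(f == 0.5)
  if (length(i_hit)) {
    p50 <- t[min(i_hit)] # plateau at exactly 0.5: earliest time
  } else {
    i_above <- min(which(f > 0.5))
    if (i_above == 1L) {
      p50 <- t[1L] # already past 50% at the first observation
    } else {
      i_below <- i_above - 1L
      p50 <- t[i_below] + (0.5 - f[i_below]) /
        (f[i_above] - f[i_below]) * (t[i_above] - t[i_below])
    }
  }
  structure(list(p50 = p50, reached = TRUE,
                 n_pupae_final = curve$n_pupae_final,
                 qualifies = qualifies), class = "p50_result")
}

#' Per-vial P50 statistics from a long event table
#'
#' Splits a long event table into vials and computes the P50 result and
#' final pupariation fraction for each.
#'
#' @param events long-format event table with columns `genotype`, `diet`,
#'   `vial`, `obs_time_h`, `cum_pupae`, `n_seeded` (an optional `gene`
#'   column is carried through)
#' @return data frame with one row per vial: labels, `p50`, `reached`,
#'   `n_pupae_final`, `n_seeded`, `qualifies`, `frac_final`
#' @export
vial_stats <- function(events) {
  req <- c("genotype", "diet", "vial", "obs_time_h", "cum_pupae", "n_seeded")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop_param("missing columns: ", paste(miss, collapse = ", "))
  has_gene <- "gene" %in% names(events)
  keys <- c(if (has_gene) "gene", "genotype", "diet", "vial")
  split_idx <- split(seq_len(nrow(events)),
                     interaction(events[keys], drop = TRUE, lex.order = TRUE))
  rows <- lapply(split_idx, function(ix) {
    sub <- events[ix, ]
    sub <- sub[order(sub$obs_time_h), ]
    cv <- pup_curve(sub$obs_time_h, sub$cum_pupae, sub$n_seeded[1],
                    genotype = sub$genotype[1], diet = sub$diet[1],
                    vial = sub$vial[1])
    r <- p50_time(cv)
    out <- data.frame(genotype = sub$genotype[1], diet = sub$diet[1],
                      vial = sub$vial[1], p50 = r$p50, reached = r$reached,
                      n_pupae_final = r$n_pupae_final,
                      n_seeded = cv$n_seeded, qualifies = r$qualifies,
                      frac_final = cv$cum_fraction[length(cv$cum_fraction)])
    if (has_gene) out <- cbind(gene = sub$gene[1], out)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
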