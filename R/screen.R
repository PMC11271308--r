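#' Screen classification thresholds
#'
#' Numeric cut-offs for the hit-calling decision tree. A "delay" call
#' requires the excess delay (or the normal-diet delay versus control)
#' to be at least `delay_h` hours in magnitude and significant at
#' `alpha` on a replicate-level test; half a day separates biological
#' delay from scoring granularity at the daily screen cadence. "Partial
#' arrest" is a final pupariation fraction in (0, `arrest_partial`);
#' "full arrest" is a pooled final fraction of at most `arrest_full`.
#'
#' @param delay_h minimum delay in hours to call a delay phenotype
#' @param alpha two-sided significance level for the delay tests
#' @param arrest_partial upper bound (exclusive) of the partial-arrest
#'   final-fraction window; consistent with P50 being undefined below 0.5
#' @param arrest_full pooled final fraction at or below which arrest is
#'   called full
#' @return list of thresholds, class `screen_thresholds`
#' @export
screen_thresholds <- function(delay_h = 12, alpha = 0.05,
                              arrest_partial = 0.5, arrest_full = 0) {
  structure(list(
    delay_h = check_number(delay_h, "delay_h", min = 0),
    alpha = check_prob(alpha, "alpha"),
    arrest_partial = check_prob(arrest_partial, "arrest_partial"),
    arrest_full = check_prob(arrest_full, "arrest_full")
  ), class = "screen_thresholds")
}

# two-sample p-value robust to zero replicate variance (daily scoring
# can make every vial's interpolated P50 identical): a non-zero mean
# difference with no replicate scatter is treated as certain
safe_t_p <- function(g, cc) {
  if (length(g) < 2L || length(cc) < 2L) return(NA_real_)
  if (stats::sd(g) < 1e-12 && stats::sd(cc) < 1e-12)
    return(if (abs(mean(g) - mean(cc)) > 1e-12) 0 else 1)
  tryCatch(t.test(g, cc)$p.value, error = function(e) NA_real_)
}

qualifying_p50s <- function(vs, genotype, diet) {
  sel <- vs$genotype == genotype & vs$diet == diet & vs$qualifies & vs$reached
  vs$p50[sel]
}

cell_or_stop <- function(p50s, genotype, diet) {
  if (length(p50s) == 0L)
    stop(errorCondition(
      paste0("insufficient replicates: no qualifying vial with P50 for ",
             genotype, " on ", diet),
      class = c("hsdquant_insufficient_replicates", "error")))
  p50s
}

#' Sugar-dependent excess developmental delay
#'
#' The screen's hit statistic: the high-sugar-minus-normal-diet delay of
#' a knockdown genotype minus the same difference in controls,
#' `(P50_g,HSD - P50_g,ND) - (P50_c,HSD - P50_c,ND)`, computed on
#' replicate-mean P50s. Vials with fewer than three pupae, or that never
#' reach 50% pupariation, are excluded before averaging. The standard
#' error is propagated from the replicate SDs of the four cells.
#'
#' @param events long event table covering the knockdown and control
#'   genotypes on both diets (see [vial_stats()] for columns)
#' @param genotype knockdown genotype label
#' @param control control genotype label
#' @param nd,hsd diet labels for normal and high-sugar diet
#' @return list of class `delay_stat`: `genotype`, `delay_nd`,
#'   `delay_hsd` (knockdown minus control P50 per diet), `excess_delay`,
#'   `se`, and the per-cell replicate P50s
#' @export
excess_delay <- function(events, genotype, control = "control",
                         nd = "1x", hsd = "5x") {
  vs <- if (is.data.frame(events) && "p50" %in% names(events)) events
        else vial_stats(events)
  cells <- list(
    g_nd = cell_or_stop(qualifying_p50s(vs, genotype, nd), genotype, nd),
    g_hsd = cell_or_stop(qualifying_p50s(vs, genotype, hsd), genotype, hsd),
    c_nd = cell_or_stop(qualifying_p50s(vs, control, nd), control, nd),
    c_hsd = cell_or_stop(qualifying_p50s(vs, control, hsd), control, hsd))
  m <- vapply(cells, mean, numeric(1))
  # variance of a replicate mean; 0 when a cell has a single replicate
  v <- vapply(cells, function(x)
    if (length(x) > 1L) stats::var(x) / length(x) else 0, numeric(1))
  structure(list(
    genotype = genotype,
    delay_nd = m[["g_nd"]] - m[["c_nd"]],
    delay_hsd = m[["g_hsd"]] - m[["c_hsd"]],
    excess_delay = (m[["g_hsd"]] - m[["g_nd"]]) - (m[["c_hsd"]] - m[["c_nd"]]),
    se = sqrt(sum(v)),
    cells = cells
  ), class = "delay_stat")
}

# pooled final pupariation fraction across all vials (0-pupae vials
# count toward arrest evidence)
pooled_fraction <- function(vs, genotype, diet) {
  sel <- vs$genotype == genotype & vs$diet == diet
  if (!any(sel)) return(NA_real_)
  sum(vs$n_pupae_final[sel]) / sum(vs$n_seeded[sel])
}

# phenotype severity on one diet: "full" > "partial" > "delay" > "none"
diet_phenotype <- function(vs, genotype, control, diet, thresholds) {
  frac <- pooled_fraction(vs, genotype, diet)
  if (frac <= thresholds$arrest_full) return(list(pheno = "full", p = NA_real_))
  if (frac < thresholds$arrest_partial) return(list(pheno = "partial", p = NA_real_))
  g <- qualifying_p50s(vs, genotype, diet)
  cc <- qualifying_p50s(vs, control, diet)
  if (length(g) == 0L || length(cc) == 0L)
    return(list(pheno = "none", p = NA_real_))
  d <- mean(g) - mean(cc)
  p <- safe_t_p(g, cc)
  delayed <- is.finite(d) && d >= thresholds$delay_h &&
    !is.na(p) && p < thresholds$alpha
  list(pheno = if (delayed) "delay" else "none", p = p)
}

#' Classify a screen gene into the sugar-dependence hit classes
#'
#' Deterministic decision tree over the phenotype on each diet.
#' Phenotype severity per diet is full arrest (pooled final pupariation
#' fraction at the full cut-off), partial arrest (fraction below 0.5),
#' or delay (P50 shift versus control at least `delay_h` hours and
#' significant). Sugar-dependent (`SD_*`) classes require no phenotype
#' on the normal diet; partially-sugar-dependent (`PSD_*`) classes
#' require a phenotype on both diets with the stronger one on high
#' sugar. Genotypes with no high-sugar phenotype, and severity patterns
#' outside the recognised progressions, are called `"none"`.
#'
#' @inheritParams excess_delay
#' @param thresholds a [screen_thresholds()] object
#' @return list of class `hit_call`: `genotype`, `class`, per-diet
#'   phenotypes and pooled fractions, the `delay_stat` when all four
#'   cells exist, and the delay-test p-values
#' @export
classify_hit <- function(events, genotype, control = "control",
                         thresholds = screen_thresholds(),
                         nd = "1x", hsd = "5x") {
  vs <- if (is.data.frame(events) && "p50" %in% names(events)) events
        else vial_stats(events)
  if (!any(vs$genotype == control))
    stop_param("missing control reference genotype: ", control)
  ph_nd <- diet_phenotype(vs, genotype, control, nd, thresholds)

  # HSD severity: arrest from pooled fractions; otherwise a "delay" call
  # uses the diet-effect-corrected excess delay with the genotype x diet
  # interaction test as its replicate-level significance test
  frac_hsd <- pooled_fraction(vs, genotype, hsd)
  ds <- tryCatch(excess_delay(vs, genotype, control, nd = nd, hsd = hsd),
                 hsdquant_insufficient_replicates = function(e) NULL)
  ph_hsd <- list(pheno = "none", p = NA_real_)
  if (frac_hsd <= thresholds$arrest_full) {
    ph_hsd$pheno <- "full"
  } else if (frac_hsd < thresholds$arrest_partial) {
    ph_hsd$pheno <- "partial"
  } else if (!is.null(ds)) {
    cells <- ds$cells
    if (all(lengths(cells) >= 2L)) {
      if (all(vapply(cells, stats::sd, numeric(1)) < 1e-12)) {
        # no replicate scatter in any cell: the interaction term is
        # certain whenever the excess delay is non-zero
        p <- if (abs(ds$excess_delay) > 1e-12) 0 else 1
      } else {
        tb <- data.frame(
          genotype = rep(c("g", "g", "c", "c"), lengths(cells)),
          diet = rep(c(nd, hsd, nd, hsd), lengths(cells)),
          p50 = unlist(cells, use.names = FALSE))
        p <- tryCatch(interaction_test(tb), error = function(e) NA_real_)
        if (is.nan(p)) p <- NA_real_
      }
      if (is.finite(ds$excess_delay) &&
          ds$excess_delay >= thresholds$delay_h &&
          !is.na(p) && p < thresholds$alpha) {
        ph_hsd$pheno <- "delay"
        ph_hsd$p <- p
      }
    }
  }

  cls <- switch(ph_nd$pheno,
    none = switch(ph_hsd$pheno,
      full = "SD_full_arrest", partial = "SD_partial_arrest",
      delay = "SD_delay", none = "none"),
    delay = switch(ph_hsd$pheno,
      full = "PSD_delay_then_full_arrest",
      partial = "PSD_delay_then_partial_arrest",
      "none"),
    partial = if (ph_hsd$pheno == "full") "PSD_partial_then_full_arrest" else "none",
    full = "none")

  structure(list(
    genotype = genotype, class = cls,
    pheno_nd = ph_nd$pheno, pheno_hsd = ph_hsd$pheno,
    frac_nd = pooled_fraction(vs, genotype, nd),
    frac_hsd = pooled_fraction(vs, genotype, hsd),
    delay_stat = ds, p_nd = ph_nd$p, p_hsd = ph_hsd$p
  ), class = "hit_call")
}

#' Classify every gene of a screen event table
#'
#' @param events long event table with a `gene` column; the control
#'   genotype rows must carry `gene == control`
#' @inheritParams classify_hit
#' @return data frame with one row per gene: `gene`, `class`, per-diet
#'   phenotype labels and pooled fractions, `excess_delay`, `se`
#' @export
classify_screen <- function(events, control = "control",
                            thresholds = screen_thresholds(),
                            nd = "1x", hsd = "5x") {
  vs <- vial_stats(events)
  genes <- setdiff(unique(vs$gene), control)
  ctrl_vs <- vs[vs$gene == control, setdiff(names(vs), "gene")]
  rows <- lapply(genes, function(g) {
    sub <- vs[vs$gene == g, setdiff(names(vs), "gene")]
    hc <- classify_hit(rbind(sub, ctrl_vs), genotype = g,
                       control = control, thresholds = thresholds,
                       nd = nd, hsd = hsd)
    data.frame(gene = g, class = hc$class,
               pheno_nd = hc$pheno_nd, pheno_hsd = hc$pheno_hsd,
               frac_nd = hc$frac_nd, frac_hsd = hc$frac_hsd,
               excess_delay = if (is.null(hc$delay_stat)) NA_real_
                              else hc$delay_stat$excess_delay,
               se = if (is.null(hc$delay_stat)) NA_real_
                    else hc$delay_stat$se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a screen's hit table
#'
#' Computes the hit rate, per-class counts, the split between
#' sugar-dependent-only and partially-sugar-dependent hits, and
#' annotation breakdowns (human orthologs, disease association) per
#' group. Hit genes missing from the annotation table are counted as
#' unannotated with a warning.
#'
#' @param hits data frame with columns `gene` and `class` (from
#'   [classify_screen()])
#' @param n_genes_screened total genes screened (denominator of the hit
#'   rate); defaults to the number of rows in `hits`
#' @param annotations optional data frame keyed by `gene` with logical
#'   columns such as `has_human_ortholog`, `disease_associated`,
#'   `obesity_diabetes_associated`
#' @return list of class `screen_summary`: `n_genes_screened`, `n_hits`,
#'   `hit_rate_pct` (one decimal), `class_counts`, `n_sd_only`, `n_psd`,
#'   and per-annotation counts/percentages for all hits and for the
#'   partially-sugar-dependent subset (integer percent)
#' @examples
#' hits <- data.frame(gene = paste0("g", 1:4),
#'                    class = c("none", "SD_delay", "none", "SD_full_arrest"))
#' screen_summary(hits)$hit_rate_pct # 50
#' @export
screen_summary <- function(hits, n_genes_screened = nrow(hits),
                           annotations = NULL) {
  stopifnot(all(c("gene", "class") %in% names(hits)))
  n_genes_screened <- check_count(n_genes_screened, "n_genes_screened", min = 0L)
  hit_rows <- hits[hits$class != "none", , drop = FALSE]
  n_hits <- nrow(hit_rows)
  hit_rate <- if (n_genes_screened > 0) round(100 * n_hits / n_genes_screened, 1) else 0.0
  cls <- factor(hit_rows$class, levels = hit_classes())
  class_counts <- as.list(table(cls))
  sd_only <- startsWith(hit_rows$class, "SD_")
  n_sd <- sum(sd_only)
  n_psd <- n_hits - n_sd

  ann_summary <- NULL
  if (!is.null(annotations) && n_hits > 0) {
    stopifnot("gene" %in% names(annotations))
    missing <- setdiff(hit_rows$gene, annotations$gene)
    if (length(missing))
      warning(length(missing), " hit gene(s) not in the annotation table; ",
              "counted as unannotated")
    flags <- setdiff(names(annotations), "gene")
    idx <- match(hit_rows$gene, annotations$gene)
    ann_summary <- lapply(setNames(flags, flags), function(fl) {
      v <- as.logical(annotations[[fl]][idx])
      v[is.na(v)] <- FALSE
      psd_v <- v[!sd_only]
      list(n_hits = sum(v),
           pct_hits = if (n_hits) round(100 * sum(v) / n_hits) else 0L,
           n_psd = sum(psd_v),
           pct_psd = if (n_psd) round(100 * sum(psd_v) / n_psd) else 0L)
    })
  }
  structure(list(
    n_genes_screened = n_genes_screened, n_hits = n_hits,
    hit_rate_pct = hit_rate, class_counts = class_counts,
    n_sd_only = n_sd, n_psd = n_psd, annotations = ann_summary
  ), class = "screen_summary")
}

#' Two-way ANOVA interaction test for genotype x diet
#'
#' Tests the genotype-by-diet interaction of replicate P50 times: the
#' formal version of the excess-delay statistic being non-zero.
#'
#' @param p50_tbl data frame with columns `genotype`, `diet`, `p50`
#'   (one row per replicate vial); 2 genotypes x 2 diets, at least two
#'   replicates per cell
#' @return p-value of the interaction term
#' @export
interaction_test <- function(p50_tbl) {
  stopifnot(all(c("genotype", "diet", "p50") %in% names(p50_tbl)))
  tab <- table(p50_tbl$genotype, p50_tbl$diet)
  if (any(dim(tab) != 2L))
    stop_param("interaction test needs exactly 2 genotypes and 2 diets")
  if (any(tab < 2L))
    stop_param("at least 2 replicates required in every genotype x diet cell")
  fit <- aov(p50 ~ genotype * diet, data = transform(
    p50_tbl, genotype = factor(genotype), diet = factor(diet)))
  tt <- summary(fit)[[1]]
  p <- tt[["Pr(>F)"]][grep(":", rownames(tt))]
  unname(p)
}

#' Larval-crowding check: P50 versus rearing density
#'
#' One-factor analysis of variance of replicate P50 times across larval
#' density groups, per diet, to verify that crowding does not shift
#' pupariation timing.
#'
#' @param p50_tbl data frame with columns `density`, `p50` and
#'   optionally `diet`
#' @return data frame with one row per diet: `diet`, `p`, plus a
#'   `means` attribute (per diet x density mean P50)
#' @export
crowding_check <- function(p50_tbl) {
  stopifnot(all(c("density", "p50") %in% names(p50_tbl)))
  if (!"diet" %in% names(p50_tbl)) p50_tbl$diet <- "all"
  per_diet <- lapply(split(p50_tbl, p50_tbl$diet), function(sub) {
    dens <- factor(sub$density)
    if (nlevels(dens) < 2L)
      stop_param("crowding check needs at least 2 density groups")
    p <- oneway.test(p50 ~ dens, data = sub, var.equal = TRUE)$p.value
    means <- tapply(sub$p50, dens, mean)
    list(p = p, means = means)
  })
  out <- data.frame(diet = names(per_diet),
                    p = vapply(per_diet, `[[`, numeric(1), "p"))
  rownames(out) <- NULL
  attr(out, "means") <- lapply(per_diet, `[[`, "means")
  out
}
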