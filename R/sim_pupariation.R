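#' Parameters for the pupariation-timing simulator
#'
#' Describes one genotype's pupariation behaviour under the vial assay:
#' larvae are seeded into replicate vials, each larva pupariates at a
#' random time (normal, truncated at zero) or arrests permanently, and
#' cumulative pupae are scored on a fixed observation grid.
#'
#' @param n_vials number of replicate vials
#' @param larvae_per_vial larvae seeded per vial
#' @param p50_base median pupariation time on the normal diet, hours
#'   after egg laying (h AEL)
#' @param sd_pup between-larva SD of pupariation time, hours
#' @param excess_delay extra delay (hours) on the high-sugar diet beyond
#'   the diet effect seen in controls; 0 for a control genotype
#' @param control_diet_effect delay (hours) that the high-sugar diet adds
#'   in controls
#' @param arrest_prob probability that a larva never pupariates
#' @param obs_interval hours between scoring observations (the follow-up
#'   assays scored every 4-8 h; the screen scored daily)
#' @param obs_end last observation time, h AEL
#' @param genotype_delay constant genotype-intrinsic delay (hours) added
#'   on both diets; used to plant partially-sugar-dependent phenotypes
#' @param seed integer seed
#' @return an object of class `pup_sim_params`
#' @export
pup_sim_params <- function(n_vials = 5, larvae_per_vial = 30,
                           p50_base = 110, sd_pup = 6,
                           excess_delay = 0, control_diet_effect = 40,
                           arrest_prob = 0, obs_interval = 8,
                           obs_end = 320, genotype_delay = 0, seed = 1) {
  p <- list(
    n_vials = check_count(n_vials, "n_vials"),
    larvae_per_vial = check_count(larvae_per_vial, "larvae_per_vial"),
    p50_base = check_number(p50_base, "p50_base", min = 0),
    sd_pup = check_number(sd_pup, "sd_pup", min = 0, strict_min = TRUE),
    excess_delay = check_number(excess_delay, "excess_delay"),
    control_diet_effect = check_number(control_diet_effect, "control_diet_effect"),
    arrest_prob = check_prob(arrest_prob, "arrest_prob"),
    obs_interval = check_number(obs_interval, "obs_interval",
                                min = 0, strict_min = TRUE),
    obs_end = check_number(obs_end, "obs_end", min = 0, strict_min = TRUE),
    genotype_delay = check_number(genotype_delay, "genotype_delay"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(p, class = "pup_sim_params")
}

# one truncated-normal event time per larva; arrested larvae get +Inf
r_pup_times <- function(n, median_h, sd_h, arrest_prob) {
  t <- rnorm(n, mean = median_h, sd = sd_h)
  while (any(neg <- t < 0)) # truncate at 0: resample negatives
    t[neg] <- rnorm(sum(neg), mean = median_h, sd = sd_h)
  arrested <- runif(n) < arrest_prob
  t[arrested] <- Inf
  t
}

#' Simulate a pupariation event table for one genotype x diet cell
#'
#' Event times are drawn from a normal distribution truncated at zero
#' with median `p50_base` plus, on the high-sugar diet, the control diet
#' effect and the genotype's excess delay. Arrest is a per-larva
#' Bernoulli censoring event. Cumulative pupae are then scored on the
#' observation grid, exactly as the vial assay records them.
#'
#' @param params a [pup_sim_params()] object
#' @param genotype genotype label carried into the table
#' @param diet diet label; the high-sugar shift is applied when the label
#'   matches `hsd_label`
#' @param hsd_label which diet label denotes the high-sugar diet
#' @return a long-format data frame with columns `genotype`, `diet`,
#'   `vial`, `obs_time_h`, `cum_pupae`, `n_seeded`; cumulative counts are
#'   non-decreasing within each vial and never exceed `n_seeded`
#' @examples
#' ev <- sim_pupariation(pup_sim_params(seed = 7), "ctrl", "1x")
#' head(ev)
#' @export
sim_pupariation <- function(params, genotype = "control", diet = "1x",
                            hsd_label = "5x") {
  if (!inherits(params, "pup_sim_params"))
    stop_param("params must be a pup_sim_params object")
  median_h <- params$p50_base + params$genotype_delay +
    if (identical(diet, hsd_label)) params$control_diet_effect + params$excess_delay else 0
  grid <- seq(params$obs_interval, params$obs_end, by = params$obs_interval)
  local_seed(params$seed, {
    out <- lapply(seq_len(params$n_vials), function(v) {
      tt <- r_pup_times(params$larvae_per_vial, median_h, params$sd_pup,
                        params$arrest_prob)
      cum <- vapply(grid, function(g) sum(tt <= g), integer(1))
      data.frame(genotype = genotype, diet = diet, vial = v,
                 obs_time_h = grid, cum_pupae = cum,
                 n_seeded = params$larvae_per_vial)
    })
    do.call(rbind, out)
  })
}

#' Hit classes recognised by the screen
#'
#' `SD_*` classes show a phenotype only on the high-sugar diet; `PSD_*`
#' (partially sugar-dependent) classes show a phenotype on both diets
#' with the stronger one on high sugar.
#'
#' @return character vector of class labels (excluding `"none"`)
#' @export
hit_classes <- function() {
  c("SD_full_arrest", "SD_partial_arrest", "SD_delay",
    "PSD_delay_then_full_arrest", "PSD_delay_then_partial_arrest",
    "PSD_partial_then_full_arrest")
}

# per-class planted effect defaults (hours / arrest probabilities);
# chosen well clear of the classification thresholds
plant_effects <- function(class, excess_delay_h, nd_delay_h,
                          arrest_nd, arrest_hsd) {
  eff <- list(excess_delay = 0, nd_delay = 0, arrest_nd = 0, arrest_hsd = 0)
  switch(class,
    none = NULL,
    SD_full_arrest = { eff$arrest_hsd <- 1 },
    SD_partial_arrest = { eff$arrest_hsd <- arrest_hsd },
    SD_delay = { eff$excess_delay <- excess_delay_h },
    PSD_delay_then_full_arrest = {
      eff$nd_delay <- nd_delay_h; eff$arrest_hsd <- 1
    },
    PSD_delay_then_partial_arrest = {
      eff$nd_delay <- nd_delay_h; eff$arrest_hsd <- arrest_hsd
    },
    PSD_partial_then_full_arrest = {
      eff$arrest_nd <- arrest_nd; eff$arrest_hsd <- 1
    },
    stop_param("unknown planted class: ", class)
  )
  eff
}

#' Simulate a multi-gene screen event table with planted hit classes
#'
#' Generates, for each gene in `gene_table`, knockdown vials on both
#' diets with the planted phenotype, plus one shared control genotype.
#' Defaults reflect the daily-scored screen cadence.
#'
#' @param gene_table data frame with column `gene` and `class` (one of
#'   [hit_classes()] or `"none"`); optional numeric columns
#'   `excess_delay_h`, `nd_delay_h`, `arrest_nd`, `arrest_hsd` override
#'   the per-class effect defaults
#' @param params baseline [pup_sim_params()]; per-gene effects are
#'   planted on top of it. The default observation interval for the
#'   screen is daily, so pass `obs_interval = 24` for screen cadence.
#' @param excess_delay_h,nd_delay_h default planted delays (hours)
#' @param arrest_partial default planted arrest probability for partial
#'   arrest phenotypes (final pupariation fraction approx 1 - this)
#' @return list with `events` (long event table including the control
#'   genotype, knockdown genotype labels equal to gene names) and
#'   `truth` (the resolved per-gene planted class and effects)
#' @export
sim_screen <- function(gene_table, params = pup_sim_params(obs_interval = 24),
                       excess_delay_h = 24, nd_delay_h = 24,
                       arrest_partial = 0.75) {
  stopifnot(is.data.frame(gene_table), all(c("gene", "class") %in% names(gene_table)))
  bad <- setdiff(gene_table$class, c(hit_classes(), "none"))
  if (length(bad))
    stop_param("unknown planted class label(s): ", paste(bad, collapse = ", "))

  ctrl <- rbind(
    sim_pupariation(modify_params(params, seed = params$seed * 2L + 11L),
                    "control", "1x"),
    sim_pupariation(modify_params(params, seed = params$seed * 2L + 12L),
                    "control", "5x"))
  ctrl <- cbind(gene = "control", ctrl)

  truth <- gene_table
  tabs <- vector("list", nrow(gene_table))
  for (i in seq_len(nrow(gene_table))) {
    g <- gene_table$gene[i]
    eff <- plant_effects(gene_table$class[i],
      pick(gene_table, i, "excess_delay_h", excess_delay_h),
      pick(gene_table, i, "nd_delay_h", nd_delay_h),
      pick(gene_table, i, "arrest_nd", arrest_partial),
      pick(gene_table, i, "arrest_hsd", arrest_partial))
    if (is.null(eff)) eff <- list(excess_delay = 0, nd_delay = 0,
                                  arrest_nd = 0, arrest_hsd = 0)
    s_nd <- modify_params(params, seed = params$seed + 1000L + 2L * i,
                          genotype_delay = eff$nd_delay,
                          arrest_prob = eff$arrest_nd)
    s_hsd <- modify_params(params, seed = params$seed + 1001L + 2L * i,
                           genotype_delay = eff$nd_delay,
                           excess_delay = eff$excess_delay,
                           arrest_prob = eff$arrest_hsd)
    tabs[[i]] <- cbind(gene = g, rbind(
      sim_pupariation(s_nd, genotype = g, diet = "1x"),
      sim_pupariation(s_hsd, genotype = g, diet = "5x")))
  }
  list(events = rbind(ctrl, do.call(rbind, tabs)), truth = truth)
}

pick <- function(df, i, col, default) {
  if (col %in% names(df) && !is.na(df[[col]][i])) df[[col]][i] else default
}

modify_params <- function(params, ...) {
  repl <- list(...)
  p <- unclass(params)
  p[names(repl)] <- repl
  do.call(pup_sim_params, p)
}
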