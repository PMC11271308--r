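#' Validate a phosphosite table against its channel design
#'
#' @param table data frame with `site_id`, `protein_id` and one positive
#'   abundance column per channel
#' @param design data frame with `channel`, `genotype`, `treatment`,
#'   `replicate`; every channel must be a column of `table` and every
#'   genotype x treatment cell must have at least 2 replicates
#' @return list of class `phospho_table` with elements `table`, `design`
#' @export
phospho_table <- function(table, design) {
  stopifnot(is.data.frame(table), is.data.frame(design))
  req <- c("channel", "genotype", "treatment", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop_param("design missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("site_id", "protein_id") %in% names(table)))
    stop_param("table must have site_id and protein_id columns")
  absent <- setdiff(design$channel, names(table))
  if (length(absent))
    stop_param("design channels missing from table: ", paste(absent, collapse = ", "))
  ab <- as.matrix(table[, design$channel, drop = FALSE])
  if (!is.numeric(ab)) stop_param("abundance columns must be numeric")
  bad <- which(ab <= 0 | is.na(ab), arr.ind = TRUE)
  if (nrow(bad))
    stop_param("non-positive abundance at row ", bad[1, 1],
               ", channel ", design$channel[bad[1, 2]])
  reps <- table(design$genotype, design$treatment)
  if (any(reps < 2L))
    stop_param("every genotype x treatment cell needs >= 2 replicates")
  structure(list(table = table, design = design), class = "phospho_table")
}

as_phospho <- function(x, design = NULL) {
  if (inherits(x, "phospho_table")) return(x)
  if (is.list(x) && !is.data.frame(x) && !is.null(x$table) && !is.null(x$design))
    return(phospho_table(x$table, x$design))
  phospho_table(x, design)
}

#' Equalize channel totals
#'
#' Scales every abundance channel so that all channel totals equal the
#' grand mean of the original totals, the usual correction for unequal
#' labeling or loading. Within-channel ratios are preserved exactly.
#'
#' @param pt a [phospho_table()] (or a list with `table` and `design`)
#' @return a normalized `phospho_table`
#' @export
normalize_channels <- function(pt) {
  pt <- as_phospho(pt)
  ch <- pt$design$channel
  totals <- vapply(ch, function(k) sum(pt$table[[k]]), numeric(1))
  if (any(totals == 0)) stop_param("channel with zero total abundance")
  target <- mean(totals)
  for (k in ch) pt$table[[k]] <- pt$table[[k]] * (target / totals[[k]])
  pt
}

#' Per-site one-factor ANOVA across conditions
#'
#' One-way analysis of variance of log2 abundances per phosphosite over
#' the supplied condition grouping. Sites with no within-group variance
#' and equal group means return p = 1 by convention.
#'
#' @param pt a [phospho_table()]
#' @param grouping factor of length `nrow(design)` assigning each
#'   channel to a group; defaults to genotype x treatment
#' @return numeric vector of p-values, one per site
#' @export
site_anova <- function(pt, grouping = NULL) {
  pt <- as_phospho(pt)
  if (is.null(grouping))
    grouping <- interaction(pt$design$genotype, pt$design$treatment, drop = TRUE)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop_param("need at least 2 groups")
  if (any(table(grouping) < 2L)) stop_param("every group needs >= 2 channels")
  ab <- log2(as.matrix(pt$table[, pt$design$channel, drop = FALSE]))
  apply(ab, 1, function(y) {
    if (all(tapply(y, grouping, stats::var) == 0)) {
      gm <- tapply(y, grouping, mean)
      if (diff(range(gm)) == 0) return(1) # perfectly flat: no evidence
      return(0)
    }
    oneway.test(y ~ grouping, var.equal = TRUE)$p.value
  })
}

direction_from_fc <- function(fc, theta, down_rule) {
  lo <- if (down_rule == "reciprocal") 1 / (1 + theta) else 1 - theta
  ifelse(fc >= 1 + theta, "up", ifelse(fc <= lo, "down", "none"))
}

#' Insulin-response fold changes and >30%-change calls per site
#'
#' For one genotype, computes the insulin/mock fold change of replicate
#' means per site (on channel-normalized abundances) and classifies each
#' site as `up` (fold change at least `1 + theta`), `down`, or `none`.
#' The default down-rule is the reciprocal threshold `1/(1 + theta)`
#' (symmetric on the log scale); `down_rule = "raw"` uses `1 - theta`.
#' A per-site Welch t-test on log2 abundances (insulin vs mock) is
#' attached for volcano-style outputs; the direction call itself is
#' fold-change-only.
#'
#' @param pt a [phospho_table()]
#' @param genotype genotype label present in the design
#' @param theta response threshold (default 0.30)
#' @param down_rule `"reciprocal"` (default) or `"raw"`
#' @param normalize whether to equalize channel totals first
#' @return data frame of class `response_changes`: `site_id`,
#'   `protein_id`, `fold_change`, `log2_fc`, `direction`, `p`
#' @export
insulin_response <- function(pt, genotype, theta = 0.30,
                             down_rule = c("reciprocal", "raw"),
                             normalize = TRUE) {
  pt <- as_phospho(pt)
  down_rule <- match.arg(down_rule)
  theta <- check_number(theta, "theta", min = 0, strict_min = TRUE)
  des <- pt$design
  if (!genotype %in% des$genotype)
    stop_param("genotype not in design: ", genotype)
  if (normalize) pt <- normalize_channels(pt)
  ins <- des$channel[des$genotype == genotype & des$treatment == "insulin"]
  mock <- des$channel[des$genotype == genotype & des$treatment == "mock"]
  if (length(ins) == 0L || length(mock) == 0L)
    stop_param("genotype ", genotype, " lacks an insulin or mock arm")
  mi <- rowMeans(pt$table[, ins, drop = FALSE])
  mm <- rowMeans(pt$table[, mock, drop = FALSE])
  fc <- mi / mm
  li <- log2(as.matrix(pt$table[, ins, drop = FALSE]))
  lm_ <- log2(as.matrix(pt$table[, mock, drop = FALSE]))
  p <- vapply(seq_len(nrow(pt$table)), function(i) {
    yi <- li[i, ]; ym <- lm_[i, ]
    if (stats::sd(yi) == 0 && stats::sd(ym) == 0)
      return(if (mean(yi) == mean(ym)) 1 else 0)
    tryCatch(t.test(yi, ym)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(site_id = pt$table$site_id,
                    protein_id = pt$table$protein_id,
                    fold_change = fc, log2_fc = log2(fc),
                    direction = direction_from_fc(fc, theta, down_rule),
                    p = p)
  attr(out, "genotype") <- genotype
  attr(out, "theta") <- theta
  attr(out, "down_rule") <- down_rule
  class(out) <- c("response_changes", class(out))
  out
}

#' Count up/down insulin-response changes
#'
#' @param responses a data frame with `site_id` and `direction` (e.g.
#'   from [insulin_response()])
#' @return list of class `response_set`: `genotype`, `up_sites`,
#'   `down_sites`, `n_up`, `n_down`, `n_total` (= `n_up + n_down`)
#' @export
count_changes <- function(responses) {
  if (nrow(responses) == 0L)
    return(structure(list(genotype = attr(responses, "genotype"),
                          up_sites = character(0), down_sites = character(0),
                          n_up = 0L, n_down = 0L, n_total = 0L),
                     class = "response_set"))
  stopifnot(all(c("site_id", "direction") %in% names(responses)))
  up <- responses$site_id[responses$direction == "up"]
  down <- responses$site_id[responses$direction == "down"]
  structure(list(genotype = attr(responses, "genotype"),
                 up_sites = up, down_sites = down,
                 n_up = length(up), n_down = length(down),
                 n_total = length(up) + length(down)),
            class = "response_set")
}

#' Knockdown-dependent subset of the control insulin response
#'
#' Control-regulated phosphosites that show no response (`direction ==
#' "none"`) in the knockdown genotypes: with `mode = "all"` (default) a
#' site must be unresponsive in every knockdown; `mode = "any"` requires
#' only one. The dependence fraction is reported as the percentage of
#' the control response, rounded to an integer.
#'
#' @param control_responses [insulin_response()] output for the control
#' @param kd_responses a single response table or list of them, one per
#'   knockdown; must cover the same site universe as the control
#' @param mode `"all"` or `"any"`
#' @return list of class `dependent_set`: `sites`, `n`, `n_up`,
#'   `n_down` (direction taken from the control), `n_control_total`,
#'   `fraction_pct`
#' @export
dependent_set <- function(control_responses, kd_responses,
                          mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (is.data.frame(kd_responses)) kd_responses <- list(kd_responses)
  if (length(kd_responses) == 0L) stop_param("no knockdown responses supplied")
  universe <- sort(control_responses$site_id)
  for (kd in kd_responses)
    if (!identical(sort(kd$site_id), universe))
      stop_param("site universes differ between control and knockdown")
  reg <- control_responses[control_responses$direction != "none", ]
  none_in <- vapply(kd_responses, function(kd) {
    idx <- match(reg$site_id, kd$site_id)
    kd$direction[idx] == "none"
  }, logical(nrow(reg)))
  none_in <- matrix(none_in, nrow = nrow(reg))
  dep <- if (mode == "all") apply(none_in, 1, all) else apply(none_in, 1, any)
  sel <- reg[dep, ]
  n_ctrl <- nrow(reg)
  structure(list(
    sites = sel$site_id, n = nrow(sel),
    n_up = sum(sel$direction == "up"),
    n_down = sum(sel$direction == "down"),
    n_control_total = n_ctrl,
    fraction_pct = if (n_ctrl) round(100 * nrow(sel) / n_ctrl) else 0L
  ), class = "dependent_set")
}

#' Collapse phosphosites to unique proteins
#'
#' Proteins repeated because of multiple regulated sites are removed,
#' leaving the unique protein set.
#'
#' @param sites character vector of site ids
#' @param mapping data frame with `site_id`, `protein_id` (a response
#'   table works)
#' @return character vector of unique protein ids
#' @export
dedupe_proteins <- function(sites, mapping) {
  stopifnot(all(c("site_id", "protein_id") %in% names(mapping)))
  idx <- match(sites, mapping$site_id)
  if (anyNA(idx))
    stop_param("unmapped site id(s): ",
               paste(head(sites[is.na(idx)], 3), collapse = ", "))
  unique(mapping$protein_id[idx])
}

#' Venn region counts for protein sets
#'
#' Counts, for every combination of set memberships, the elements
#' belonging to exactly those sets. Region counts sum to the size of the
#' union.
#'
#' @param sets named list of >= 2 character vectors
#' @return data frame with one row per non-empty membership pattern:
#'   one logical column per set, `region` (a `"A&B"`-style label) and
#'   `count`
#' @export
venn_overlap <- function(sets) {
  if (length(sets) < 2L) stop_param("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  memb <- matrix(memb, nrow = length(univ), dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  counts <- apply(patterns, 1, function(p)
    sum(apply(memb, 1, function(m) all(m == p))))
  out <- cbind(patterns,
               region = apply(patterns, 1, function(p)
                 paste(names(sets)[as.logical(p)], collapse = "&")),
               count = as.integer(counts))
  rownames(out) <- NULL
  out
}

#' Pathway overrepresentation by two-sided Fisher's exact test
#'
#' Tests each pathway's overlap with the hit proteins against the
#' background universe via the 2x2 table (hit-and-in-pathway,
#' hit-not-in-pathway, background-in-pathway, rest). Pathways are
#' intersected with the background first; pathways disjoint from the
#' background are skipped with a warning.
#'
#' @param hits character vector of hit proteins, a subset of `background`
#' @param background character vector: the tested protein universe
#' @param pathways named list of character vectors (e.g. [read_gmt()])
#' @param alpha significance cut-off on the raw p-value
#' @param p_adjust optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) keeps raw p
#' @return data frame: `pathway`, `n_overlap`, `n_hits`, `n_pathway_bg`,
#'   `n_background`, `odds_ratio`, `p`, `p_adj`, `significant`
#' @export
enrichment <- function(hits, background, pathways, alpha = 0.05,
                       p_adjust = "none") {
  hits <- unique(hits)
  background <- unique(background)
  if (length(background) == 0L) stop_param("empty background")
  if (!all(hits %in% background))
    stop_param("hits must be a subset of the background")
  rows <- lapply(names(pathways), function(nm) {
    path <- intersect(unique(pathways[[nm]]), background)
    if (length(path) == 0L) {
      warning("pathway '", nm, "' shares no genes with the background; skipped")
      return(NULL)
    }
    a <- length(intersect(hits, path))
    b <- length(hits) - a
    c_ <- length(path) - a
    d <- length(background) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "two.sided")
    data.frame(pathway = nm, n_overlap = a, n_hits = length(hits),
               n_pathway_bg = length(path),
               n_background = length(background),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(pathway = character(0), n_overlap = integer(0),
                      n_hits = integer(0), n_pathway_bg = integer(0),
                      n_background = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- if (identical(p_adjust, "none")) out$p
               else stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < alpha
  out[order(out$p), ]
}
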