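read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop_param("input file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_param(basename(path), ": missing column(s) ",
               paste(miss, collapse = ", "))
  df
}

#' Write a table as TSV
#'
#' UTF-8, tab-separated, header row, `.` decimal — the package's
#' interchange format for all tables.
#'
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a pupariation event table
#'
#' Expects the long format written by the simulators: one row per
#' observation with columns `genotype`, `diet`, `vial`, `obs_time_h`,
#' `cum_pupae`, `n_seeded` (plus optional `gene`). Cumulative counts
#' must be non-decreasing in time within each vial and never exceed the
#' seeded count; violations are reported with their row number.
#'
#' @param path TSV file path
#' @return validated data frame
#' @export
read_events <- function(path) {
  df <- read_tsv_checked(path, c("genotype", "diet", "vial", "obs_time_h",
                                 "cum_pupae", "n_seeded"))
  keys <- c(intersect("gene", names(df)), "genotype", "diet", "vial")
  for (ix in split(seq_len(nrow(df)),
                   interaction(df[keys], drop = TRUE))) {
    ord <- ix[order(df$obs_time_h[ix])]
    d <- diff(df$cum_pupae[ord])
    if (any(d < 0))
      stop_param(basename(path), ": cumulative pupae decrease at row ",
                 ord[which(d < 0)[1] + 1L])
    over <- df$cum_pupae[ord] > df$n_seeded[ord]
    if (any(over))
      stop_param(basename(path), ": cum_pupae exceeds n_seeded at row ",
                 ord[which(over)[1]])
  }
  df
}

#' Read a phosphosite table and its channel design
#'
#' @param path TSV with `site_id`, `protein_id` and one abundance column
#'   per channel
#' @param design_path TSV with `channel`, `genotype`, `treatment`,
#'   `replicate`
#' @return a [phospho_table()]
#' @export
read_phospho <- function(path, design_path) {
  tab <- read_tsv_checked(path, c("site_id", "protein_id"))
  des <- read_tsv_checked(design_path, c("channel", "genotype",
                                         "treatment", "replicate"))
  phospho_table(tab, des)
}

#' Read a plate-reader table
#'
#' @param path TSV with `well`, `role` (standard / sample / blank),
#'   `known_conc`, `absorbance`
#' @return validated data frame
#' @export
read_plate <- function(path) {
  df <- read_tsv_checked(path, c("well", "role", "known_conc", "absorbance"))
  bad <- !df$role %in% c("standard", "sample", "blank")
  if (any(bad))
    stop_param(basename(path), ": unknown role '", df$role[which(bad)[1]],
               "' at row ", which(bad)[1])
  no_conc <- df$role == "standard" & is.na(df$known_conc)
  if (any(no_conc))
    stop_param(basename(path), ": standard without known_conc at row ",
               which(no_conc)[1])
  df
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated. Lines with fewer than three fields are rejected with
#' their line number.
#'
#' @param path GMT file path
#' @return named list of character vectors, with a `description`
#'   attribute
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_param("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop_param(basename(path), ": GMT line ", which(short)[1],
               " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Read a gene annotation table
#'
#' Ortholog/disease annotations keyed by gene, with logical columns such
#' as `has_human_ortholog`, `disease_associated`,
#' `obesity_diabetes_associated`.
#'
#' @param path TSV file path
#' @return data frame with a `gene` column and logical flags
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, "gene")
  for (cn in setdiff(names(df), "gene")) df[[cn]] <- as.logical(df[[cn]])
  df
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' Channels are stored one per page as 16-bit grayscale, scaled by a
#' shared factor recorded in the channel order sidecar; `read_image_tiff`
#' restores the original intensities.
#'
#' @param stack an [image_stack()] of 2-D channels
#' @param path output `.tif` path (a `.channels.tsv` sidecar is written
#'   next to it with channel names and the intensity scale)
#' @return `path`, invisibly
#' @export
write_image_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack, max, numeric(1)), 1e-12)
  pages <- lapply(stack, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  write_tsv(data.frame(channel = names(stack), scale = mx),
            paste0(path, ".channels.tsv"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @return `read_image_tiff`: the restored [image_stack()] (intensities
#'   quantized to 16 bits)
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- read_tsv_checked(paste0(path, ".channels.tsv"),
                           c("channel", "scale"))
  ch <- lapply(seq_along(pages), function(i) pages[[i]] * side$scale[1])
  names(ch) <- side$channel
  image_stack(ch)
}

#' Run the seeded end-to-end synthetic demonstration pipeline
#'
#' Simulates a small screen, classifies its hits and summarises them;
#' simulates a phosphoproteomics experiment and computes per-genotype
#' response counts, the knockdown-dependent set and a toy pathway
#' enrichment; simulates a metabolite plate and quantifies its samples
#' against the fitted standard curve. All artifacts are written under
#' `out_dir` as TSV/YAML, and a run log (seed, thresholds, input
#' digests) makes the run reproducible: the same seed yields
#' byte-identical outputs.
#'
#' @param out_dir output directory (created if needed)
#' @param seed integer seed driving every simulation
#' @return invisibly, a list of the in-memory results (`screen_hits`,
#'   `screen_summary`, `response_counts`, `dependent`, `enrichment`,
#'   `plate_quant`, `paths`)
#' @export
run_demo <- function(out_dir, seed = 1) {
  seed <- check_count(seed, "seed", min = 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, paste0(...))

  # --- screen -----------------------------------------------------------
  gene_table <- data.frame(
    gene = sprintf("gene%02d", 1:8),
    class = c("none", "none", "SD_full_arrest", "SD_partial_arrest",
              "SD_delay", "PSD_delay_then_full_arrest",
              "PSD_delay_then_partial_arrest", "PSD_partial_then_full_arrest"))
  scr <- sim_screen(gene_table,
                    params = pup_sim_params(obs_interval = 24, seed = seed))
  write_tsv(scr$events, pth("screen_events.tsv"))
  hits <- classify_screen(read_events(pth("screen_events.tsv")))
  write_tsv(hits, pth("screen_hits.tsv"))
  summ <- screen_summary(hits)

  # --- phosphoproteomics -----------------------------------------------
  ph <- sim_phospho(phospho_sim_params(n_sites = 400, n_proteins = 150,
                                       noise_sd = 0.05, seed = seed + 1L))
  write_tsv(ph$table, pth("phospho_table.tsv"))
  write_tsv(ph$design, pth("phospho_design.tsv"))
  pt <- read_phospho(pth("phospho_table.tsv"), pth("phospho_design.tsv"))
  resp <- lapply(setNames(unique(pt$design$genotype),
                          unique(pt$design$genotype)),
                 function(g) insulin_response(pt, g))
  counts <- lapply(resp, count_changes)
  dep <- dependent_set(resp$control, resp[c("KD1", "KD2")])
  gmt <- split(unique(ph$table$protein_id),
               rep(c("pathway_A", "pathway_B"),
                   length.out = length(unique(ph$table$protein_id))))
  enr <- enrichment(dedupe_proteins(dep$sites, resp$control),
                    unique(ph$table$protein_id), gmt)
  write_tsv(enr, pth("enrichment.tsv"))

  # --- plate -----------------------------------------------------------
  pl <- sim_plate(c(0.2, 0.5, 1.0, 2.0), slope = 0.4, intercept = 0.05,
                  noise_sd = 0.002, seed = seed + 2L)
  write_tsv(pl$plate, pth("plate.tsv"))
  plate <- read_plate(pth("plate.tsv"))
  std <- plate[plate$role == "standard", ]
  curve <- fit_standard(std$known_conc, std$absorbance,
                        blank = plate$absorbance[plate$role == "blank"])
  samp <- plate[plate$role == "sample", ]
  quant <- data.frame(well = samp$well,
                      conc = as.numeric(conc_from_abs(curve, samp$absorbance)))
  write_tsv(quant, pth("plate_quant.tsv"))

  # --- summary + run log -----------------------------------------------
  yaml::write_yaml(list(
    screen = list(n_genes = summ$n_genes_screened, n_hits = summ$n_hits,
                  hit_rate_pct = summ$hit_rate_pct,
                  class_counts = summ$class_counts),
    phospho = lapply(counts, function(x)
      list(n_up = x$n_up, n_down = x$n_down, n_total = x$n_total)),
    dependence = list(n = dep$n, fraction_pct = dep$fraction_pct),
    standard_curve = list(model = curve$model,
                          r_squared = round(curve$r_squared, 6))
  ), pth("summary.yaml"))
  yaml::write_yaml(list(
    seed = seed,
    thresholds = unclass(screen_thresholds()),
    package_version = as.character(utils::packageVersion("hsdquant")),
    input_digests = vapply(
      c("screen_events.tsv", "phospho_table.tsv", "plate.tsv"),
      function(f) unname(tools::md5sum(pth(f))), character(1))
  ), pth("run_log.yaml"))

  invisible(list(screen_hits = hits, screen_summary = summ,
                 response_counts = counts, dependent = dep,
                 enrichment = enr, plate_quant = quant,
                 paths = normalizePath(out_dir)))
}
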