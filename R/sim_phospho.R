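#' Parameters for the phosphoproteomics simulator
#'
#' Emulates an 18-channel isobaric-labeling experiment: 3 genotypes
#' (control and two knockdowns) x 2 treatments (mock, insulin) x
#' `n_replicates` parallel treatments. A planted fraction of sites is
#' insulin-responsive in control cells; knockdown genotypes carry the
#' same effects multiplied by `blunting`.
#'
#' @param n_sites number of phosphosites
#' @param n_proteins number of proteins (site-to-protein mapping is
#'   many-to-one, round-robin)
#' @param frac_responsive fraction of sites insulin-responsive in control
#' @param mean_log2_effect log2 fold-change magnitude of a responsive
#'   site (sign drawn per site)
#' @param blunting multiplicative reduction of the effect in knockdowns
#'   (0 = fully blunted, 1 = unblunted)
#' @param n_replicates replicates per condition (>= 2)
#' @param noise_sd log2-scale measurement noise SD
#' @param seed integer seed
#' @return object of class `phospho_sim_params`
#' @export
phospho_sim_params <- function(n_sites = 1000, n_proteins = 400,
                               frac_responsive = 0.2,
                               mean_log2_effect = 1, blunting = 0.2,
                               n_replicates = 3, noise_sd = 0.1,
                               seed = 1) {
  p <- list(
    n_sites = check_count(n_sites, "n_sites"),
    n_proteins = check_count(n_proteins, "n_proteins"),
    frac_responsive = check_prob(frac_responsive, "frac_responsive"),
    mean_log2_effect = check_number(mean_log2_effect, "mean_log2_effect", min = 0),
    blunting = check_prob(blunting, "blunting"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(p, class = "phospho_sim_params")
}

#' Simulate a phosphosite quantification table with planted responses
#'
#' @param params a [phospho_sim_params()] object
#' @param genotypes genotype labels; the first is the unblunted control
#' @return list with `table` (data frame: `site_id`, `protein_id`, one
#'   abundance column per channel), `design` (data frame: `channel`,
#'   `genotype`, `treatment`, `replicate`), and `truth` (data frame of
#'   planted responsive sites: `site_id`, `direction`, `log2_effect`)
#' @export
sim_phospho <- function(params = phospho_sim_params(),
                        genotypes = c("control", "KD1", "KD2")) {
  if (!inherits(params, "phospho_sim_params"))
    stop_param("params must be a phospho_sim_params object")
  treatments <- c("mock", "insulin")
  design <- expand.grid(replicate = seq_len(params$n_replicates),
                        treatment = treatments, genotype = genotypes,
                        stringsAsFactors = FALSE)[, 3:1]
  design$channel <- sprintf("C%02d", seq_len(nrow(design)))
  design <- design[, c("channel", "genotype", "treatment", "replicate")]

  n <- params$n_sites
  site_id <- sprintf("site_%04d", seq_len(n))
  protein_id <- sprintf("prot_%04d", ((seq_len(n) - 1) %% params$n_proteins) + 1)

  local_seed(params$seed, {
    base_log2 <- rnorm(n, mean = 10, sd = 1)
    n_resp <- round(params$frac_responsive * n)
    resp_idx <- if (n_resp > 0) sort(sample.int(n, n_resp)) else integer(0)
    dir_sign <- integer(n)
    dir_sign[resp_idx] <- sample(c(-1L, 1L), n_resp, replace = TRUE)
    effect <- dir_sign * params$mean_log2_effect

    abund <- matrix(NA_real_, n, nrow(design),
                    dimnames = list(NULL, design$channel))
    for (k in seq_len(nrow(design))) {
      blunt <- if (design$genotype[k] == genotypes[1]) 1 else params$blunting
      shift <- if (design$treatment[k] == "insulin") effect * blunt else 0
      lg <- base_log2 + shift
      if (params$noise_sd > 0)
        lg <- lg + rnorm(n, 0, params$noise_sd)
      abund[, k] <- 2^lg
    }
    truth <- data.frame(
      site_id = site_id[resp_idx],
      direction = ifelse(dir_sign[resp_idx] > 0, "up", "down"),
      log2_effect = effect[resp_idx])
    list(table = data.frame(site_id = site_id, protein_id = protein_id,
                            abund, check.names = FALSE),
         design = design, truth = truth)
  })
}
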