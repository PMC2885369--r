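#' Simulation parameters for synthetic array experiments
#'
#' Bundles every tunable of the synthetic-data generator: variant rates for
#' the genome pair, the intensity model coefficients, and replicate counts.
#' All intensity-model terms are on the log10 scale of raw scanner units.
#'
#' The intensity model for a perfect-match probe is
#' \deqn{y = level + slope (\Delta G - \overline{\Delta G}) + strain + \epsilon}
#' where `level` is `baseline_log10` plus the amount-class term (gDNA mode)
#' or the per-gene expression draw (transcript mode), `strain` is minus a
#' per-probe SFP effect draw for mismatched strain-B targets, and
#' \eqn{\epsilon \sim N(0, noise\_sd)}. The result is soft-capped at
#' `saturation_ceiling` (smooth soft-minimum, sharpness
#' `saturation_sharpness`) and floored at `crosshyb_floor`; the mismatch
#' (MM) probe follows the same model minus `mm_penalty`.
#'
#' @param snp_rate per-bp SNP rate between the two genomes (default 0.004,
#'   i.e. 4 SNPs/kb, the expected divergence in probe target regions).
#' @param indel_rate per-bp short indel rate.
#' @param duplication_rate per-gene-sized-segment (5 kb) tandem duplication
#'   rate in the second genome.
#' @param baseline_log10 log10 intensity of an average probe at the
#'   reference amount class (5 ug).
#' @param affinity_slope log10 intensity change per kcal/mol of duplex
#'   \eqn{\Delta G} (negative: stronger binding, brighter probe).
#' @param amount_effect named numeric vector of additive log10 terms for
#'   the gDNA amount classes "1", "5", "40" (ug of labeled product).
#' @param saturation_ceiling log10 ceiling the signal is soft-capped at
#'   (`Inf` disables saturation).
#' @param saturation_sharpness sharpness of the soft-minimum cap.
#' @param sfp_effect_mean,sfp_effect_sd mean and SD (log10 units, natural
#'   scale) of the per-probe lognormal intensity loss of a mismatched
#'   target; the mean must be positive (an SFP lowers intensity).
#' @param sfp_affinity_coupling couples the SFP effect to binding affinity:
#'   the effect is multiplied by `exp(coupling * (dG - mean(dG)))`, so with
#'   a positive coupling strong binders (more negative \eqn{\Delta G}) lose
#'   less signal. 0 disables.
#' @param mm_penalty log10 reduction of the MM probe relative to PM for a
#'   perfectly matched target.
#' @param crosshyb_floor log10 level of the non-specific
#'   cross-hybridization background at the reference amount class; the
#'   background adds to the specific signal on the raw scale, so it floors
#'   weak signals smoothly (`-Inf` disables it).
#' @param crosshyb_amount_slope how fast the cross-hybridization level
#'   grows with the amount term relative to the specific signal
#'   (default 2: non-specific binding does not saturate the way specific
#'   targets do, so high amounts inflate the background and erode the
#'   intensity deficit of mismatched targets).
#' @param noise_sd SD of the Gaussian log10 noise (>= 0).
#' @param expression_law list with `p_low`, `low_mean`, `high_mean`, `sd`:
#'   per-gene log10 expression is drawn from a two-component normal mixture
#'   per tissue, putting a controllable fraction of probe sets below the
#'   2.5 expression cutoff.
#' @param frag_dropout_rate per-fragment probability that a 100-250 bp
#'   amplification fragment drops out in strain B (amplification
#'   polymorphism mode; plants clustered false positives). 0 disables.
#' @param frag_dropout_effect log10 intensity loss of probes in a dropped
#'   fragment.
#' @param frag_len_range length range (bp) of amplification fragments.
#' @param reps_gdna,reps_rna biological replicates per strain for gDNA
#'   (default 4) and transcript (default 5) hybridizations.
#' @return an object of class `sfp_sim_params` (a validated list).
#' @examples
#' p <- sim_params(snp_rate = 0.002, noise_sd = 0.1)
#' p$snp_rate
#' @export
sim_params <- function(snp_rate = 0.004,
                       indel_rate = 2e-4,
                       duplication_rate = 0,
                       baseline_log10 = 2.8,
                       affinity_slope = -0.08,
                       amount_effect = c("1" = -0.6, "5" = 0, "40" = 0.8),
                       saturation_ceiling = 4.1,
                       saturation_sharpness = 2,
                       sfp_effect_mean = 0.5,
                       sfp_effect_sd = 0.35,
                       sfp_affinity_coupling = 0,
                       mm_penalty = 0.45,
                       crosshyb_floor = 1.6,
                       crosshyb_amount_slope = 2,
                       noise_sd = 0.15,
                       expression_law = list(p_low = 0.4, low_mean = 1.5,
                                             high_mean = 3.2, sd = 0.4),
                       frag_dropout_rate = 0,
                       frag_dropout_effect = 0.5,
                       frag_len_range = c(100, 250),
                       reps_gdna = 4,
                       reps_rna = 5) {
  stopifnot(
    snp_rate >= 0, snp_rate <= 1,
    indel_rate >= 0, indel_rate <= 1,
    duplication_rate >= 0, duplication_rate <= 1,
    frag_dropout_rate >= 0, frag_dropout_rate <= 1,
    noise_sd >= 0,
    sfp_effect_mean > 0, sfp_effect_sd >= 0,
    saturation_sharpness > 0,
    reps_gdna >= 1, reps_rna >= 1,
    length(frag_len_range) == 2, frag_len_range[1] <= frag_len_range[2]
  )
  if (is.null(names(amount_effect)) || any(names(amount_effect) == ""))
    stop("amount_effect must be a named vector of amount classes")
  structure(
    list(snp_rate = snp_rate, indel_rate = indel_rate,
         duplication_rate = duplication_rate,
         baseline_log10 = baseline_log10, affinity_slope = affinity_slope,
         amount_effect = amount_effect,
         saturation_ceiling = saturation_ceiling,
         saturation_sharpness = saturation_sharpness,
         sfp_effect_mean = sfp_effect_mean, sfp_effect_sd = sfp_effect_sd,
         sfp_affinity_coupling = sfp_affinity_coupling,
         mm_penalty = mm_penalty, crosshyb_floor = crosshyb_floor,
         crosshyb_amount_slope = crosshyb_amount_slope,
         noise_sd = noise_sd, expression_law = expression_law,
         frag_dropout_rate = frag_dropout_rate,
         frag_dropout_effect = frag_dropout_effect,
         frag_len_range = frag_len_range,
         reps_gdna = as.integer(reps_gdna), reps_rna = as.integer(reps_rna)),
    class = "sfp_sim_params"
  )
}

#' @export
print.sfp_sim_params <- function(x, ...) {
  cat("Synthetic array simulation parameters\n")
  cat(sprintf("  variant rates: SNP %.4g/bp, indel %.4g/bp, dup %.4g/segment\n",
              x$snp_rate, x$indel_rate, x$duplication_rate))
  cat(sprintf("  signal: baseline %.2f, affinity slope %.3g/(kcal/mol), noise SD %.3g\n",
              x$baseline_log10, x$affinity_slope, x$noise_sd))
  cat(sprintf("  SFP effect: %.2f +/- %.2f log10; MM penalty %.2f; floor %.2f; ceiling %s\n",
              x$sfp_effect_mean, x$sfp_effect_sd, x$mm_penalty,
              x$crosshyb_floor,
              if (is.finite(x$saturation_ceiling))
                sprintf("%.2f", x$saturation_ceiling) else "off"))
  cat(sprintf("  replicates: %d (gDNA) / %d (transcript)\n",
              x$reps_gdna, x$reps_rna))
  invisible(x)
}

#' Expected SFP fraction of probes from SNP density
#'
#' For 25-mer probes on a genome diverged at `snp_rate` SNPs per bp, the
#' expected number of SNPs under a probe footprint is `probe_len *
#' snp_rate` (0.1 at 4 SNPs/kb: one expected SFP probe per 10 probes), and
#' the probability that a probe overlaps at least one SNP is
#' `1 - (1 - snp_rate)^probe_len`.
#'
#' @param snp_rate SNPs per bp.
#' @param probe_len probe length in bp (default 25).
#' @return a list with `snps_per_probe` and `sfp_probability`.
#' @examples
#' expected_sfp_density(0.004)$snps_per_probe  # 0.1
#' @export
expected_sfp_density <- function(snp_rate, probe_len = 25) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, probe_len >= 1)
  list(snps_per_probe = probe_len * snp_rate,
       sfp_probability = 1 - (1 - snp_rate)^probe_len)
}
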