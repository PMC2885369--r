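#' Nearest-neighbor DNA duplex parameter table
#'
#' Loads the unified nearest-neighbor thermodynamic parameter set for DNA
#' duplexes (SantaLucia's 1998 unified set): enthalpy (kcal/mol) and
#' entropy (cal/(mol K)) for the 16 dinucleotide stacks plus duplex
#' initiation terms for G.C and A.T terminal pairs. The table ships as a
#' plain TSV and round-trips through [read_nn_table()]/[write_nn_table()]
#' bit-exactly.
#'
#' @param path path to the parameter TSV; defaults to the copy shipped
#'   with the package.
#' @return a data.frame with columns `element`, `dH_kcal_mol`,
#'   `dS_cal_mol_K`; stacks are named by their 5'->3' top-strand
#'   dinucleotide.
#' @examples
#' head(nn_parameter_table())
#' @export
nn_parameter_table <- function(path = system.file("extdata",
                                                  "nn_unified_1998.tsv",
                                                  package = "sfpkit")) {
  read_nn_table(path)
}

#' @rdname nn_parameter_table
#' @export
read_nn_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric"))
  need <- c("element", "dH_kcal_mol", "dS_cal_mol_K")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  stacks <- tab$element[!startsWith(tab$element, "init_")]
  if (length(stacks) != 16)
    stop("parameter table must contain all 16 dinucleotide stacks")
  tab
}

#' @rdname nn_parameter_table
#' @param tab a parameter data.frame to write.
#' @export
write_nn_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Nearest-neighbor duplex free energy
#'
#' Computes the binding stability \eqn{\Delta G(T)} of each probe paired
#' with its exact complement, as the sum over dinucleotide stacks of
#' \eqn{\Delta H - T \Delta S} (with \eqn{\Delta S} converted from
#' cal/(mol K) to kcal/(mol K)) plus the two terminal initiation terms.
#' The default temperature is the 50 degree C wash temperature (323.15 K).
#' No salt correction is applied.
#'
#' @param sequence character vector of DNA sequences (A/C/G/T, length >= 2).
#' @param temperature temperature in kelvin (default 323.15).
#' @param table parameter table from [nn_parameter_table()].
#' @return numeric vector of free energies in kcal/mol (negative =
#'   stronger binding).
#' @examples
#' delta_g(c("ACGTACGTACGTACGTACGTACGTA", "AA"))
#' @export
delta_g <- function(sequence, temperature = 323.15,
                    table = nn_parameter_table()) {
  if (any(nchar(sequence) < 2))
    stop("sequences must have length >= 2")
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequences contain ambiguous or non-ACGT bases")
  dg_el <- setNames(table$dH_kcal_mol - temperature * table$dS_cal_mol_K / 1000,
                    table$element)
  init <- c(A = dg_el[["init_AT"]], T = dg_el[["init_AT"]],
            C = dg_el[["init_GC"]], G = dg_el[["init_GC"]])
  vapply(sequence, function(s) {
    n <- nchar(s)
    stacks <- substring(s, 1:(n - 1), 2:n)
    sum(dg_el[stacks]) + init[[substr(s, 1, 1)]] + init[[substr(s, n, n)]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter probes by binding affinity
#'
#' Keeps weaker-binding probes, those with \eqn{\Delta G} strictly greater
#' than the threshold. Very strong binders stay bright even over a
#' mismatched target, hiding SFPs; the default cutoff of -26 kcal/mol
#' removes them.
#'
#' @param records data.frame with `probe_id` and `delta_g` columns.
#' @param threshold free-energy cutoff in kcal/mol (default -26).
#' @return character vector of retained probe ids.
#' @examples
#' affinity_filter(data.frame(probe_id = c("a", "b"),
#'                            delta_g = c(-24, -27)))
#' @export
affinity_filter <- function(records, threshold = -26) {
  stopifnot(all(c("probe_id", "delta_g") %in% names(records)))
  records$probe_id[records$delta_g > threshold]
}

#' Binding-affinity histograms per probe group
#'
#' Tabulates, for each named group of probes (e.g. all unique probes,
#' correctly called SFPs, false negatives), the fraction of the group per
#' \eqn{\Delta G} bin, for comparison of affinity distributions between
#' called and missed SFPs.
#'
#' @param records data.frame with `probe_id` and `delta_g`.
#' @param groups named list of probe-id vectors.
#' @param binwidth bin width in kcal/mol (default 0.5).
#' @return a data.frame with `bin_start`, `bin_end`, and one frequency
#'   column per group; each non-empty group's frequencies sum to 1.
#' @export
affinity_histogram <- function(records, groups, binwidth = 0.5) {
  stopifnot(all(c("probe_id", "delta_g") %in% names(records)))
  dg <- setNames(records$delta_g, records$probe_id)
  all_vals <- unlist(lapply(groups, function(g) dg[g]), use.names = FALSE)
  all_vals <- all_vals[is.finite(all_vals)]
  if (length(all_vals) == 0) {
    warning("all groups are empty")
    return(data.frame(bin_start = numeric(), bin_end = numeric()))
  }
  lo <- floor(min(all_vals) / binwidth) * binwidth
  hi <- ceiling(max(all_vals) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth, by = binwidth)
  out <- data.frame(bin_start = head(breaks, -1), bin_end = tail(breaks, -1))
  for (nm in names(groups)) {
    v <- dg[groups[[nm]]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warning("group '", nm, "' is empty")
      out[[nm]] <- rep(NA_real_, nrow(out))
    } else {
      cnt <- table(cut(v, breaks, right = FALSE, include.lowest = TRUE))
      out[[nm]] <- as.numeric(cnt) / length(v)
    }
  }
  out
}
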