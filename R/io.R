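#' Read and write FASTA sequence files
#'
#' `read_fasta()` parses a FASTA file into a named character vector,
#' uppercasing sequences and rejecting characters outside A/C/G/T/N; an
#' empty file yields an empty vector with a warning. `write_fasta()`
#' writes named sequences; the pair round-trips exactly.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA at ", path, ": ",
                         conditionMessage(e)))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("record ", i, " ('", names(seqs)[i],
         "') contains non-ACGTN characters")
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a TSV with required columns
#'
#' Header-bearing, tab-separated, locale-independent ('.' decimal) reader
#' used for all tabular artifacts; errors name any missing mandatory
#' column and unknown columns are preserved.
#'
#' @param path file path.
#' @param required character vector of mandatory column names.
#' @return a data.frame.
#' @export
read_tsv_checked <- function(path, required = character(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname read_tsv_checked
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write and read an intensity matrix with its sample-metadata sidecar
#'
#' The matrix goes to `<path>` as a TSV with a `feature` column
#' (`<probe_id>:PM|MM`) and one column per sample; the metadata sidecar
#' (`sample_id`, `strain`, `mode`, `amount_or_tissue`, `replicate`) goes
#' to `<meta_path>`. Reading checks that every sample column is described
#' in the sidecar.
#'
#' @param x an `intensity_matrix`.
#' @param path,meta_path file paths for the matrix and the sidecar.
#' @export
write_intensities <- function(x, path, meta_path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(feature = rownames(x$intensity), x$intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(x$samples, meta_path)
  invisible(path)
}

#' @rdname write_intensities
#' @param probes probe table to reattach (optional; a minimal one is
#'   rebuilt from the feature ids otherwise).
#' @export
read_intensities <- function(path, meta_path, probes = NULL) {
  df <- read_tsv_checked(path, "feature")
  samples <- read_tsv_checked(meta_path,
                              c("sample_id", "strain", "mode",
                                "amount_or_tissue", "replicate"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$feature
  unknown <- setdiff(colnames(mat), samples$sample_id)
  if (length(unknown))
    stop("sample column(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  samples <- samples[match(colnames(mat), samples$sample_id), ]
  rownames(samples) <- NULL
  if (is.null(probes)) {
    ids <- sub(":(PM|MM)$", "", rownames(mat))
    probes <- data.frame(probe_id = unique(ids), stringsAsFactors = FALSE)
  }
  structure(list(intensity = mat, samples = samples, probes = probes,
                 mode = samples$mode[1], seed = NA),
            class = "intensity_matrix")
}

#' Run the full simulate-annotate-call-evaluate pipeline
#'
#' Chains the package end to end on a synthetic genome pair and writes
#' every artifact (FASTA genomes, variant/probe/intensity/annotation/call
#' tables, evaluation and ROC TSVs, a uniqueness summary, and the
#' resolved configuration with every seed used) into `out_dir`. Reruns
#' with the same configuration are identical. A stage failure stops with
#' an error naming the stage.
#'
#' @param config a list (or path to a YAML file) with entries: `out_dir`;
#'   `seed`; `genome_length`; `n_sets`; `probes_per_set`; `set_span`;
#'   `mode` ("gdna"/"transcript"); `amount` (amount class or tissue);
#'   `caller` ("sam", "anova", "snep"); `threshold`; optional `params`
#'   (overrides passed to [sim_params()]); optional `roc_thresholds`.
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1, genome_length = 200000, n_sets = 100,
                   probes_per_set = 11, set_span = 400, mode = "gdna",
                   amount = 5, caller = "sam", threshold = 0.378,
                   params = list(), roc_thresholds = NULL)
  for (nm in names(defaults))
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- do.call(sim_params, config$params)

  sim <- stage("simulate", {
    gp <- generate_genome_pair(config$genome_length, params, config$seed)
    probes <- design_probe_sets(gp, config$n_sets, config$probes_per_set,
                                config$set_span, config$seed + 1L)
    im <- simulate_intensities(probes, gp, config$mode, config$amount,
                               params, config$seed + 2L)
    write_fasta(setNames(gp$seq_a, gp$chrom), pth("genome_a.fasta"))
    write_fasta(setNames(gp$seq_b, gp$chrom), pth("genome_b.fasta"))
    write_tsv(cbind(chrom = gp$chrom, gp$variants), pth("variants.tsv"))
    write_tsv(probes[, c("probe_id", "set_id", "chrom", "start", "strand",
                         "pm_sequence", "mm_sequence")],
              pth("probes.tsv"))
    write_intensities(im, pth("intensities.tsv"), pth("samples.tsv"))
    list(gp = gp, probes = probes, im = im)
  })
  gp <- sim$gp; probes <- sim$probes; im <- sim$im

  ann <- stage("annotate", {
    a <- classify_probes(probes, gp$seq_a)
    a <- predict_sfp_truth(a, probes, gp$seq_b)
    write_tsv(a, pth("annotation.tsv"))
    write_tsv(annotation_summary(a, probes), pth("uniqueness_summary.tsv"))
    a
  })

  lm <- log_transform(im)
  calls <- stage("call", {
    cs <- switch(config$caller,
      sam = sam_call(lm, delta = config$threshold,
                     seed = config$seed + 3L),
      anova = anova_call(lm, alpha = config$threshold),
      snep = {
        sets <- if (config$mode == "gdna")
          group_random(probes$probe_id, seed = config$seed + 3L)
        else probes$set_id
        snep_call(lm, alpha = config$threshold, sets = sets)
      },
      stop("unknown caller: ", config$caller))
    write_tsv(data.frame(cs, caller = attr(cs, "caller"),
                         threshold = attr(cs, "threshold")),
              pth("calls.tsv"))
    cs
  })

  stage("evaluate", {
    # restrict to unique probes with defined truth, the callable universe
    uni <- ann$probe_id[ann$class_a == "unique"]
    truth <- data.frame(probe_id = ann$probe_id,
                        sfp_truth = ann$sfp_truth)[ann$probe_id %in% uni, ]
    cs_u <- calls[calls$probe_id %in% uni, ]
    ev <- evaluate_calls(cs_u, truth)
    write_tsv(as.data.frame(ev), pth("evaluation.tsv"))
    if (config$caller != "sam") {
      ths <- config$roc_thresholds %||% 10^seq(-12, -1, by = 1)
      roc <- roc_curve(cs_u[, c("probe_id", "statistic")], truth,
                       thresholds = ths)
    } else {
      ths <- config$roc_thresholds %||% seq(1.5, 0.05, by = -0.05)
      fit <- sam_fit(lm, seed = config$seed + 3L)
      csl <- lapply(ths, function(dd) {
        cc <- sam_call(fit, delta = dd)
        cc[cc$probe_id %in% uni, ]
      })
      roc <- roc_curve(csl, truth)
    }
    write_tsv(as.data.frame(roc), pth("roc.tsv"))
    wt <- window_track(probes[probes$probe_id %in% uni, ], truth, cs_u,
                       window = 1e6, step = 1e5)
    write_tsv(as.data.frame(wt), pth("window_track.tsv"))
  })

  stage("report", {
    config$params <- unclass(params)
    yaml::write_yaml(config, pth("resolved_config.yaml"))
    write_tsv(data.frame(
      stage = c("genome", "probes", "intensities", "calls"),
      seed = config$seed + 0:3), pth("seed_manifest.tsv"))
  })

  invisible(list(dir = config$out_dir,
                 files = list.files(config$out_dir, full.names = TRUE)))
}
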