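#' Analysis configuration
#'
#' Bundle of thresholds used across the pipeline. The recency threshold
#' (proportion of nucleotide divergence below which a retrocopy is dismissed
#' as too young to have been vetted by selection) and the bootstrap replicate
#' count come from the study design; the remaining defaults are operational
#' choices documented in the methods vignette.
#'
#' @param recency_threshold Dismiss retrocopies with uncorrected p-distance
#'   to the parental copy strictly below this proportion. Default 0.02.
#' @param bootstrap_replicates Number of codon-column bootstrap replicates.
#'   Default 100.
#' @param bootstrap_support_min Minimum bootstrap support (percent) for an
#'   X/Y origin verdict. Default 70.
#' @param orf_length_ratio_min Minimum ORF length relative to the sex-linked
#'   reference for an "intact" call. Default 0.95.
#' @param min_reads_expressed Minimum assigned reads in a tissue to count the
#'   copy as expressed there. Default 10.
#' @param testis_fold_min Fold excess of the testis level over the best
#'   non-testis tissue for a testis-specific call. Default 5.
#' @param synteny_min_shared_flanks Minimum shared, order-consistent flanking
#'   orthologs for two loci to be called syntenic. Default 2.
#' @param mismatch_tolerance Maximum mismatches for a read to be assigned.
#'   Default 2.
#' @param random_seed Seed applied by [run_pipeline()] and the simulators.
#' @return Object of class \code{"analysis_config"}.
#' @export
analysis_config <- function(recency_threshold = 0.02,
                            bootstrap_replicates = 100,
                            bootstrap_support_min = 70,
                            orf_length_ratio_min = 0.95,
                            min_reads_expressed = 10,
                            testis_fold_min = 5,
                            synteny_min_shared_flanks = 2,
                            mismatch_tolerance = 2,
                            random_seed = 1L) {
  cfg <- list(recency_threshold = recency_threshold,
              bootstrap_replicates = as.integer(bootstrap_replicates),
              bootstrap_support_min = bootstrap_support_min,
              orf_length_ratio_min = orf_length_ratio_min,
              min_reads_expressed = min_reads_expressed,
              testis_fold_min = testis_fold_min,
              synteny_min_shared_flanks = as.integer(synteny_min_shared_flanks),
              mismatch_tolerance = mismatch_tolerance,
              random_seed = as.integer(random_seed))
  num <- vapply(cfg[setdiff(names(cfg), "random_seed")], as.numeric, 0)
  if (any(num <= 0)) stop("all thresholds must be strictly positive")
  if (cfg$recency_threshold >= 1) stop("recency_threshold must be < 1")
  if (cfg$bootstrap_support_min > 100) stop("bootstrap_support_min must be <= 100")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path File ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return An \code{analysis_config}.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
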