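# End-to-end pipeline: simulate -> QC -> call -> benchmark, with a run
# manifest for reproducibility.

#' Run the full pipeline
#'
#' Runs the simulator (or loads provided inputs), computes the capture QC
#' report, calls variants with the model ensemble, benchmarks against the
#' truth set, and writes all artifacts (FASTA/BED/SAM/FASTQ/VCF/JSON plus
#' a run manifest) to `out_dir`. Identical configuration and seed produce
#' identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()]; its `seed` drives every stage.
#' @param models Model ensemble for [call_targets()].
#' @param caller A [caller_config()].
#' @param thresholds Depth thresholds for the QC report.
#' @return A list with `sim`, `qc`, `calls`, `benchmark` and `paths`,
#'   invisibly.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), models = default_models(),
                         caller = caller_config(), thresholds = c(30, 60, 100)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simdata <- simulate_capture(sim, out_dir = out_dir)

  qc <- qc_report(simdata$reads, simdata$regions, ref = simdata$ref,
                  thresholds = thresholds,
                  min_mapq = caller$resample$min_mapq, primary_only = TRUE)
  readr::write_lines(
    jsonlite::toJSON(as.list(qc$summary), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE),
    file.path(out_dir, "qc_report.json"))

  calls <- call_targets(simdata$reads, simdata$ref, simdata$regions,
                        models = models, config = caller)
  write_vcf(calls, file.path(out_dir, "calls.vcf"), simdata$contigs)

  bench <- compare_calls(simdata$truth |> select(-"type", -"hap1", -"hap2"),
                         calls,
                         confident_regions = simdata$regions,
                         target_regions = simdata$regions,
                         ref = simdata$ref)
  readr::write_lines(
    jsonlite::toJSON(tidy(bench), dataframe = "rows", digits = NA,
                     pretty = TRUE),
    file.path(out_dir, "benchmark.json"))
  readr::write_tsv(tidy(bench), file.path(out_dir, "benchmark.tsv"))

  manifest <- list(
    package = "capcall",
    version = as.character(utils::packageVersion("capcall")),
    seed = sim$seed,
    sim_config = unclass(sim),
    caller_config = list(min_alt_fraction = caller$min_alt_fraction,
                         min_alt_reads = caller$min_alt_reads,
                         pass_qual = caller$pass_qual,
                         resample = unclass(caller$resample)),
    models = vapply(models, `[[`, character(1), "id"))
  readr::write_lines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(out_dir, "manifest.json"))

  invisible(list(sim = simdata, qc = qc, calls = calls, benchmark = bench,
                 paths = list(dir = out_dir)))
}
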