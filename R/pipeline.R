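## Orchestration: one config drives simulate -> process -> analyze, with a
## machine-readable report. Every analysis constant surfaces here as a
## named default: cleavage offset 10 nt, by-product 16 nt, piRNA band
## 24-30 nt (mode 26), maximum sequencing length 51 nt, minimum read
## length 15 nt, presence threshold 0.25 rpm, fold threshold 3, repeat
## filter 10 rpm, top 500 transcripts, normaliser length 23 nt.

#' Default run configuration
#'
#' @param seed Integer seed recorded in the config.
#' @return A nested list with `sim` (arguments for [sim_params()]),
#'   `libraries` (per-library id/genotype/conversion efficiency) and
#'   `analysis` (thresholds and windows) blocks.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(
      n_sites = 35L, guide_length = 26L, cleavage_offset = 10L,
      max_read_length = 51L, mirna_fraction = 0.2,
      conversion_efficiency = 0.9, u1_bias = 0.8,
      intermediate_length = 80L, spacer_length = 80L,
      trail_count_mean = 2, depth = 50000L
    ),
    libraries = list(
      list(id = "control", genotype = "wild_type_like", conversion_efficiency = 0.9),
      list(id = "mutant", genotype = "helicase_mutant_like", conversion_efficiency = 0.15)
    ),
    analysis = list(
      min_len = 15L, max_mm = 0L, consensus_max_mm = 3L,
      forbidden_positions = 2:10,            # protected seed positions
      pirna_range = c(24L, 30L), trail_window = c(-10L, 60L),
      delta_range = c(-20L, 30L), normalizer_length = 23L,
      theta_rpm = 0.25, theta_fold = 3, min_rpm = 10, top_n = 500L
    )
  )
}

#' Read / write a run configuration as YAML
#'
#' The config round-trips losslessly through the file.
#'
#' @param config A configuration list.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

.params_from_config <- function(config, library = NULL) {
  sim <- config$sim
  args <- sim[names(sim) %in% names(formals(sim_params))]
  if (!is.null(library) && !is.null(library$conversion_efficiency))
    args$conversion_efficiency <- library$conversion_efficiency
  do.call(sim_params, args)
}

#' Simulate all configured libraries from one reporter
#'
#' Builds a single reporter (shared across genotypes) and one library per
#' configured genotype, each with its own conversion efficiency. With an
#' output directory, writes the reporter FASTA, sites BED, per-library
#' FASTQ and truth TSV, and a JSON manifest with the seed.
#'
#' @param config Configuration list from [default_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `reporter`, `libraries` (per tag: `params`,
#'   `fragments`, `reads`) and `manifest`.
#' @export
run_simulate <- function(config = default_config(), out_dir = NULL,
                         seed = config$seed) {
  maybe_seed(seed)
  base_params <- .params_from_config(config)
  reporter <- build_reporter(base_params)

  libs <- list()
  for (lib in config$libraries) {
    params <- .params_from_config(config, lib)
    frags <- simulate_biogenesis(reporter, params)
    tag <- names(params$barcode_map)[1]
    reads <- simulate_library(frags, params, library_tag = tag)
    reads$library_tag <- rep(lib$id, nrow(reads))
    libs[[lib$id]] <- list(params = params, fragments = frags, reads = reads,
                           genotype = lib$genotype)
  }
  manifest <- list(
    seed = as.integer(seed),
    reporter = list(name = reporter$name, length = nchar(reporter$sequence),
                    n_sites = nrow(reporter$sites)),
    libraries = lapply(libs, function(l)
      list(genotype = l$genotype, depth = nrow(l$reads),
           conversion_efficiency = l$params$conversion_efficiency))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reporter(reporter, file.path(out_dir, "reporter.fa"),
                   file.path(out_dir, "sites.bed"))
    for (id in names(libs)) {
      if (nrow(libs[[id]]$reads)) {
        write_fastq(libs[[id]]$reads, file.path(out_dir, paste0(id, ".fastq")))
      } else {
        file.create(file.path(out_dir, paste0(id, ".fastq")))
      }
      write_truth(libs[[id]]$fragments, file.path(out_dir, paste0(id, "_truth.tsv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(reporter = reporter, libraries = libs, manifest = manifest)
}

#' Process one library: trim, length-filter, align, assign, classify
#'
#' The standard per-library chain: clip the barcoded 3' adapter, drop
#' reads shorter than the minimum length, align to the reporter with no
#' mismatches, assign sense reads to their nearest target site and
#' classify them into product classes.
#'
#' @param reads Data frame with `read_id`, `sequence`.
#' @param reporter A `reporter_spec`.
#' @param params The library's [sim_params()].
#' @param analysis Analysis block of the configuration.
#' @param library_tag Barcode tag used when the library was written.
#' @return A list with `trimmed`, `aligned`, `assigned` (with product
#'   `call` column) and `n_total`.
#' @export
process_library <- function(reads, reporter, params,
                            analysis = default_config()$analysis,
                            library_tag = names(params$barcode_map)[1]) {
  full_adapter <- paste0(params$barcode_map[[library_tag]], params$adapter_seq)
  trimmed <- reads
  trimmed$sequence <- trim_adapter(trimmed$sequence, full_adapter)
  trimmed <- filter_min_length(trimmed, analysis$min_len)
  aligned <- align_reads(trimmed, reporter$sequence,
                         reference_id = reporter$name,
                         max_mm = analysis$max_mm)
  assigned <- assign_sites(aligned, reporter$sites)
  assigned <- classify_products(assigned, params,
                                pirna_range = analysis$pirna_range,
                                trail_window = analysis$trail_window)
  list(trimmed = trimmed, aligned = aligned, assigned = assigned,
       n_total = nrow(reads))
}

#' Analyse simulated (or real) libraries end to end
#'
#' Runs the processing chain on every library and computes the report
#' quantities: length-distribution modes for the piRNA and contaminant
#' classes, the 5'-end distance argmax of piRNA-sized reads, the 3'-end
#' distance argmax of the by-product class, the ping-pong delta between
#' targeting-guide 5' ends and produced piRNA 5' ends, and the relative
#' 16-mer/51-mer ratios.
#'
#' @param sim Result of [run_simulate()].
#' @param config Configuration list.
#' @param out_dir Optional directory for the JSON report and profile TSVs.
#' @return A list with per-library results (`libraries`) and the `report`
#'   list that is serialised to JSON.
#' @export
run_analyze <- function(sim, config = default_config(), out_dir = NULL) {
  analysis <- config$analysis
  res <- list()
  report <- list()
  for (id in names(sim$libraries)) {
    lib <- sim$libraries[[id]]
    proc <- process_library(lib$reads, sim$reporter, lib$params, analysis)
    assigned <- proc$assigned
    n_mapped <- nrow(proc$aligned)

    pirna <- assigned[assigned$call %in% c("secondary_piRNA", "trail_piRNA"), ]
    byprod <- assigned[assigned$call == "byproduct_16mer", ]
    unmapped_len <- nchar(proc$trimmed$sequence[
      !(proc$trimmed$read_id %in% proc$aligned$read_id)])

    prof_pirna <- profile_distances(assigned, length_range = analysis$pirna_range)
    prof_by <- profile_distances(assigned,
                                 length_range = rep(lib$params$byproduct_length, 2L))
    ratios <- relative_ratios(assigned, total_mapped = n_mapped)

    M <- position_weights(pirna, "+", "five_prime", total_mapped = n_mapped)
    N <- guide_position_weights(sim$reporter)
    pp <- pingpong_score(M, N, delta_range = analysis$delta_range)

    res[[id]] <- list(process = proc, profile_pirna = prof_pirna,
                      profile_byproduct = prof_by, pingpong = pp,
                      ratios = ratios)
    report[[id]] <- list(
      n_reads = proc$n_total,
      n_mapped = n_mapped,
      modal_length_pirna = modal_length(pirna$length),
      modal_length_contaminant = modal_length(unmapped_len),
      modal_length_byproduct = modal_length(byprod$length),
      argmax_d5_pirna = profile_argmax(prof_pirna, "5p"),
      argmax_d3_byproduct = profile_argmax(prof_by, "3p"),
      pingpong_argmax = pingpong_argmax(pp),
      byproduct_ratio = ratios$byproduct_ratio,
      intermediate_ratio = ratios$intermediate_ratio
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (id in names(res)) {
      write.table(res[[id]]$profile_pirna,
                  file.path(out_dir, paste0(id, "_profile_pirna.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(libraries = res, report = report)
}

#' Simulate per-gene piRNA counts for a control/mutant comparison
#'
#' Emulates the genic-piRNA enrichment seen when slicer products fail to
#' convert: genic sense piRNAs increase by a common factor relative to the
#' contaminant microRNA population used for normalisation. Counts are
#' multinomial over genes with log-normal expression weights; each library
#' carries its own miRNA population whose 23-nt read count serves as the
#' normaliser.
#'
#' @param n_genes Number of genes.
#' @param enrichment Fold increase of genic reads relative to miRNAs in
#'   the mutant library.
#' @param depth Reads per library.
#' @param mirna_fraction Contaminant fraction of the control library.
#' @param seed Optional integer seed.
#' @return A list with `features` (per-gene counts for both libraries),
#'   `normalizer_a`/`normalizer_b` (23-nt read counts), `total_a`/`total_b`
#'   and the configured `enrichment`.
#' @export
simulate_gene_libraries <- function(n_genes = 500L, enrichment = 5,
                                    depth = 1e5, mirna_fraction = 0.2,
                                    seed = NULL) {
  maybe_seed(seed)
  w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  w <- w / sum(w)
  genes <- sprintf("gene_%04d", seq_len(n_genes))

  draw <- function(gene_share) {
    shares <- c(w * gene_share, mirna = 1 - gene_share)
    counts <- as.vector(stats::rmultinom(1, size = depth, prob = shares))
    gene_counts <- setNames(counts[seq_len(n_genes)], genes)
    n_mirna <- counts[n_genes + 1L]
    # 23-nt reads are a fixed fraction of the 21-23-nt contaminant class
    n23 <- stats::rbinom(1, n_mirna, 0.25)
    list(genes = gene_counts, n23 = n23)
  }
  gene_share_a <- 1 - mirna_fraction
  # mutant: genic reads up `enrichment`-fold relative to the miRNA anchor
  odds <- (gene_share_a / mirna_fraction) * enrichment
  gene_share_b <- odds / (1 + odds)

  a <- draw(gene_share_a)
  b <- draw(gene_share_b)
  list(
    features = data.frame(feature = genes, count_a = unname(a$genes),
                          count_b = unname(b$genes)),
    normalizer_a = a$n23, normalizer_b = b$n23,
    total_a = depth, total_b = depth, enrichment = enrichment
  )
}
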