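# Pipeline orchestration: counts -> profiles -> correlations, Harvey-Collier,
# variance explained, deviation screen; run manifest for reproducibility.

#' Assemble a run configuration
#'
#' @param input Path to a codon-count input (.spsum, .tsv, or FASTA).
#' @param out_dir Output directory for the report TSVs and manifest.
#' @param format Input dialect: \code{"auto"} (by extension), \code{"spsum"},
#'   \code{"tsv"} or \code{"fasta"}.
#' @param genetic_code NCBI translation table id (1 or 11).
#' @param min_cds Minimum CDS per record (spsum/tsv inputs).
#' @param min_aa_count Minimum codons per amino acid per record.
#' @param correlation \code{"pearson"} or \code{"spearman"}.
#' @param gc3_include_nondegenerate Include ATG/TGG in GC3 denominators.
#' @param per_sequence FASTA gene mode (one record per sequence).
#' @param seed Seed for the bootstrap deviation screen.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(input, out_dir, format = "auto", genetic_code = 11L,
                       min_cds = 50L, min_aa_count = 0L,
                       correlation = "pearson",
                       gc3_include_nondegenerate = FALSE,
                       per_sequence = FALSE, seed = 1L) {
  structure(list(input = input, out_dir = out_dir, format = format,
                 genetic_code = as.integer(genetic_code),
                 min_cds = as.integer(min_cds),
                 min_aa_count = as.integer(min_aa_count),
                 correlation = match.arg(correlation,
                                         c("pearson", "spearman")),
                 gc3_include_nondegenerate = isTRUE(gc3_include_nondegenerate),
                 per_sequence = isTRUE(per_sequence),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a key = value run-configuration file
#'
#' Plain-text lines \code{key = value}; blank lines and \code{#} comments
#' ignored. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- setNames(lapply(kv, function(p) p[[2L]]),
                   vapply(kv, function(p) p[[1L]], character(1)))
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (k in intersect(names(vals), c("genetic_code", "min_cds",
                                     "min_aa_count", "seed"))) {
    vals[[k]] <- as.integer(vals[[k]])
  }
  for (k in intersect(names(vals), c("gc3_include_nondegenerate",
                                     "per_sequence"))) {
    vals[[k]] <- toupper(vals[[k]]) %in% c("TRUE", "T", "1", "YES")
  }
  do.call(run_config, vals)
}

read_counts_any <- function(input, format = "auto", min_cds = 50L,
                            per_sequence = FALSE) {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(input))
    format <- switch(ext,
                     spsum = "spsum", tsv = "tsv", txt = "tsv",
                     fa = "fasta", fasta = "fasta", fna = "fasta",
                     stop("cannot infer input format from extension .", ext))
  }
  switch(format,
         spsum = read_cutg_spsum(input, min_cds = min_cds),
         tsv = read_counts_tsv(input, min_cds = min_cds),
         fasta = counts_from_cds_fasta(input, per_sequence = per_sequence),
         stop("unknown input format: ", format))
}

#' Run the full analysis pipeline
#'
#' Reads codon counts, applies the record and per-amino-acid filters, and
#' writes correlations.tsv, harvey_collier.tsv, variance_explained.tsv,
#' deviations.tsv and a JSON run manifest (inputs, filters, seed, version,
#' config hash) into the output directory. Deterministic given the seed.
#'
#' @param config A \code{run_config}.
#' @return Invisibly, a list with the four report data.frames and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input)) {
    stop("missing input: ", config$input)
  }
  code <- genetic_code(config$genetic_code)
  groups <- build_synonym_groups(code)
  dataset <- read_counts_any(config$input, config$format, config$min_cds,
                             config$per_sequence)
  if (length(dataset$records) == 0L) {
    stop("no records retained after filtering (min_cds = ", config$min_cds, ")")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  corr <- correlate_usage_gc3(dataset, method = config$correlation,
                              min_aa_count = config$min_aa_count,
                              groups = groups)
  lin <- linearity_report(dataset, min_aa_count = config$min_aa_count,
                          groups = groups)
  ve_codon <- variance_explained(dataset, "codon",
                                 min_aa_count = config$min_aa_count,
                                 groups = groups)
  ve_class <- variance_explained(dataset, "class",
                                 min_aa_count = config$min_aa_count,
                                 groups = groups)
  ve_tab <- rbind(cbind(level = "codon", ve_codon$table),
                  cbind(level = "class", ve_class$table))
  dev <- deviation_screen(dataset, seed = config$seed,
                          min_aa_count = config$min_aa_count, groups = groups)
  wrt <- function(df, f) utils::write.table(
    df, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wrt(corr, "correlations.tsv")
  wrt(lin, "harvey_collier.tsv")
  wrt(ve_tab, "variance_explained.tsv")
  wrt(dev, "deviations.tsv")
  cfg <- unclass(config)
  manifest <- list(
    package = "gcodon",
    version = as.character(utils::packageVersion("gcodon")),
    config = cfg,
    config_hash = config_hash(cfg),
    n_records = length(dataset$records),
    weighted_ve = list(codon = ve_codon$weighted_average,
                       class = ve_class$weighted_average),
    outputs = c("correlations.tsv", "harvey_collier.tsv",
                "variance_explained.tsv", "deviations.tsv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(correlations = corr, linearity = lin,
                 variance_explained = ve_tab, deviations = dev,
                 manifest = manifest))
}

# order-stable hash of the resolved configuration (no external digest dep)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(v, collapse = ","), ""),
             sep = "=", collapse = ";")
  # FNV-1a 32-bit over the serialized key=value string
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h <- (h %% 65536 * 16777619 +
            ((h %/% 65536 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
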