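# Codon-count input/output: CUTG species-summary (.spsum) dialect, CDS FASTA,
# TSV tables; per-group usage frequencies and GC3.

# Codon column order of CUTG species-summary files (SPSUM_LABEL from the CUTG
# format documentation), transliterated to DNA. Counts are rekeyed by codon
# string immediately on read, so nothing downstream depends on this order.
CUTG_CODON_ORDER <- c(
  "CGA", "CGC", "CGG", "CGT", "AGA", "AGG",                  # Arg
  "CTA", "CTC", "CTG", "CTT", "TTA", "TTG",                  # Leu
  "TCA", "TCC", "TCG", "TCT", "AGC", "AGT",                  # Ser
  "ACA", "ACC", "ACG", "ACT",                                # Thr
  "CCA", "CCC", "CCG", "CCT",                                # Pro
  "GCA", "GCC", "GCG", "GCT",                                # Ala
  "GGA", "GGC", "GGG", "GGT",                                # Gly
  "GTA", "GTC", "GTG", "GTT",                                # Val
  "AAA", "AAG", "AAC", "AAT",                                # Lys, Asn
  "CAA", "CAG", "CAC", "CAT",                                # Gln, His
  "GAA", "GAG", "GAC", "GAT",                                # Glu, Asp
  "TAC", "TAT", "TGC", "TGT", "TTC", "TTT",                  # Tyr, Cys, Phe
  "ATA", "ATC", "ATT", "ATG", "TGG",                         # Ile, Met, Trp
  "TAA", "TAG", "TGA")                                       # stops

#' One species' or gene's codon counts
#'
#' @param record_id Identifier (taxon id or gene id).
#' @param counts Named nonnegative numeric vector; names must cover all 64
#'   codons (any order; rekeyed internally to lexicographic order).
#' @param name Display name.
#' @param n_cds Number of coding sequences the counts summarize.
#' @return Object of class \code{codon_count_record}.
#' @export
codon_count_record <- function(record_id, counts, name = record_id,
                               n_cds = NA_integer_) {
  codons <- all_codons()
  if (is.null(names(counts)) || !setequal(names(counts), codons)) {
    stop("counts must be named by all 64 codons")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("codon counts must be finite and nonnegative")
  }
  structure(list(record_id = as.character(record_id),
                 name = as.character(name),
                 n_cds = as.integer(n_cds),
                 counts = counts[codons]),
            class = "codon_count_record")
}

#' Collection of codon-count records
#'
#' @param records List of \code{codon_count_record}s (ids must be unique).
#' @param provenance List of metadata (source path, dialect, filters).
#' @return Object of class \code{usage_dataset}.
#' @export
usage_dataset <- function(records, provenance = list()) {
  ids <- vapply(records, function(r) r$record_id, "")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  structure(list(records = setNames(records, ids), provenance = provenance),
            class = "usage_dataset")
}

#' @export
print.usage_dataset <- function(x, ...) {
  cat(sprintf("<usage_dataset> %d records", length(x$records)))
  if (!is.null(x$provenance$source)) cat(" from", x$provenance$source)
  cat("\n")
  invisible(x)
}

#' @export
length.usage_dataset <- function(x) length(x$records)

#' Read a CUTG species-summary codon-count file
#'
#' The dialect is one header line per record, \code{taxid: name: n_cds},
#' followed by one line of 64 whitespace-separated codon counts in the CUTG
#' codon order. Records based on fewer than \code{min_cds} coding sequences
#' are dropped (genome panels conventionally require 50).
#'
#' @param path File path.
#' @param min_cds Minimum number of CDS per retained record.
#' @return A \code{usage_dataset}.
#' @export
read_cutg_spsum <- function(path, min_cds = 50L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty spsum file: ", path)
    return(usage_dataset(list(), list(source = path, dialect = "spsum",
                                      min_cds = min_cds)))
  }
  if (length(lines) %% 2L != 0L) {
    stop("malformed spsum file ", path, ": odd number of non-empty lines")
  }
  records <- list()
  for (k in seq(1L, length(lines), by = 2L)) {
    hdr <- strsplit(lines[k], ":", fixed = TRUE)[[1]]
    if (length(hdr) < 3L) {
      stop("malformed spsum header at line ", k, ": ", lines[k])
    }
    taxid <- trimws(hdr[1])
    n_cds <- suppressWarnings(as.integer(trimws(hdr[length(hdr)])))
    if (is.na(n_cds)) stop("non-integer CDS count at line ", k)
    name <- trimws(paste(hdr[-c(1L, length(hdr))], collapse = ":"))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[k + 1L]),
                                                 "\\s+")[[1]]))
    if (length(vals) != 64L || any(is.na(vals))) {
      stop("expected 64 numeric codon counts at line ", k + 1L)
    }
    if (any(vals < 0)) stop("negative codon count at line ", k + 1L)
    if (n_cds < min_cds) next
    records[[length(records) + 1L]] <-
      codon_count_record(taxid, setNames(vals, CUTG_CODON_ORDER),
                         name = name, n_cds = n_cds)
  }
  usage_dataset(records, list(source = path, dialect = "spsum",
                              min_cds = min_cds))
}

#' Write a dataset in the CUTG species-summary dialect
#'
#' @param dataset A \code{usage_dataset}.
#' @param path Output path.
#' @export
write_cutg_spsum <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in dataset$records) {
    writeLines(sprintf("%s: %s: %d", r$record_id, r$name,
                       if (is.na(r$n_cds)) 0L else r$n_cds), con)
    writeLines(paste(format(r$counts[CUTG_CODON_ORDER], scientific = FALSE,
                            trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read/write a TSV codon-count table
#'
#' Header: \code{record_id}, \code{name}, \code{n_cds}, then the 64 codons in
#' lexicographic order (AAA..TTT).
#'
#' @param path File path.
#' @param min_cds Minimum CDS count per retained record (read only).
#' @return A \code{usage_dataset}.
#' @export
read_counts_tsv <- function(path, min_cds = 0L) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  codons <- all_codons()
  if (!all(c("record_id", "name", "n_cds", codons) %in% names(df))) {
    stop("counts TSV must have columns record_id, name, n_cds and all 64 codons")
  }
  keep <- which(is.na(df$n_cds) | df$n_cds >= min_cds)
  records <- lapply(keep, function(i) {
    codon_count_record(df$record_id[i],
                       setNames(as.numeric(df[i, codons]), codons),
                       name = df$name[i], n_cds = df$n_cds[i])
  })
  usage_dataset(records, list(source = path, dialect = "tsv",
                              min_cds = min_cds))
}

#' @rdname read_counts_tsv
#' @param dataset A \code{usage_dataset} to write.
#' @export
write_counts_tsv <- function(dataset, path) {
  codons <- all_codons()
  rows <- lapply(dataset$records, function(r) {
    cbind(data.frame(record_id = r$record_id, name = r$name,
                     n_cds = r$n_cds, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(r$counts[codons], codons)),
                        check.names = FALSE))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate codon counts from a CDS FASTA file
#'
#' Sequences whose length is not divisible by 3 are skipped with a warning.
#' Codons containing ambiguous bases (e.g. N) are skipped and tallied in the
#' provenance QC counter rather than guessed. Internal stop codons are counted
#' but flagged in the provenance.
#'
#' @param path FASTA file of coding sequences (DNA or RNA; RNA transliterated).
#' @param per_sequence If \code{TRUE}, one record per sequence (gene mode);
#'   otherwise all sequences pool into a single record (genome mode).
#' @param skip_start Drop the first codon of each sequence (e.g. a prepended
#'   initiation ATG) from the tallies.
#' @param trim_stop Drop one trailing stop codon per sequence.
#' @return A \code{usage_dataset}.
#' @export
counts_from_cds_fasta <- function(path, per_sequence = FALSE,
                                  skip_start = FALSE, trim_stop = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  codons <- all_codons()
  stops <- c("TAA", "TAG", "TGA")
  n_ambig <- 0L
  n_internal_stop <- 0L
  tallies <- list()
  for (i in seq_along(seqs)) {
    s <- toupper(chartr("U", "T", as.character(seqs[[i]])))
    if (nchar(s) %% 3L != 0L) {
      warning("sequence ", names(seqs)[i],
              " length not divisible by 3; skipped")
      next
    }
    cds <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
    if (trim_stop && length(cds) > 0L && cds[length(cds)] %in% stops) {
      cds <- cds[-length(cds)]
    }
    if (skip_start && length(cds) > 0L) cds <- cds[-1L]
    ok <- grepl("^[ACGT]{3}$", cds)
    n_ambig <- n_ambig + sum(!ok)
    cds <- cds[ok]
    n_internal_stop <- n_internal_stop + sum(cds %in% stops)
    tl <- table(factor(cds, levels = codons))
    tallies[[names(seqs)[i]]] <- setNames(as.numeric(tl), codons)
  }
  if (length(tallies) == 0L) stop("no usable sequences in ", path)
  prov <- list(source = path, dialect = "fasta", per_sequence = per_sequence,
               n_ambiguous_codons = n_ambig,
               n_internal_stops = n_internal_stop)
  if (n_internal_stop > 0L) {
    warning(n_internal_stop, " internal stop codon(s) counted")
  }
  if (per_sequence) {
    records <- mapply(function(id, cnt) {
      codon_count_record(id, cnt, name = id, n_cds = 1L)
    }, names(tallies), tallies, SIMPLIFY = FALSE)
  } else {
    pooled <- Reduce(`+`, tallies)
    records <- list(codon_count_record("pooled", pooled, name = "pooled",
                                       n_cds = length(tallies)))
  }
  usage_dataset(unname(records), prov)
}

#' Per-group codon usage frequencies of one record
#'
#' Frequencies are counts divided by the synonym-group total, with Ser2 and
#' Ser4 normalized independently (their codon blocks are disconnected under
#' synonymous point mutation). Groups whose total falls below
#' \code{max(1, min_aa_count)} are marked absent (\code{NA}), not zero-filled.
#'
#' @param record A \code{codon_count_record}.
#' @param min_aa_count Minimum codons of the amino acid per retained group
#'   (gene-level analyses conventionally require 10; genome level 0).
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return Object of class \code{usage_profile}: list with \code{record_id},
#'   \code{freq} (named over modelled codons; NA for absent groups),
#'   \code{group_totals} and \code{gc3}.
#' @export
per_group_frequencies <- function(record, min_aa_count = 0L,
                                  groups = build_synonym_groups()) {
  stopifnot(inherits(record, "codon_count_record"))
  freq <- c()
  totals <- c()
  for (gr in groups) {
    cnt <- record$counts[gr$codons]
    tot <- sum(cnt)
    totals[gr$label] <- tot
    f <- if (tot >= max(1, min_aa_count)) cnt / tot else rep(NA_real_,
                                                             length(cnt))
    freq[gr$codons] <- f
  }
  structure(list(record_id = record$record_id, freq = freq,
                 group_totals = totals, gc3 = gc3(record)),
            class = "usage_profile")
}

#' Third-position GC content of a codon-count record
#'
#' Fraction of counted codons whose third base is G or C. Stop codons are
#' always excluded; ATG and TGG are excluded by default because they carry no
#' synonymous signal (set \code{include_nondegenerate = TRUE} for a strict
#' all-sense-codon denominator).
#'
#' @param record A \code{codon_count_record}.
#' @param include_nondegenerate Include ATG/TGG in the tally.
#' @return GC3 in [0, 1].
#' @export
gc3 <- function(record, include_nondegenerate = FALSE) {
  stopifnot(inherits(record, "codon_count_record"))
  codons <- all_codons()
  excl <- c("TAA", "TAG", "TGA")
  if (!include_nondegenerate) excl <- c(excl, "ATG", "TGG")
  keep <- setdiff(codons, excl)
  cnt <- record$counts[keep]
  tot <- sum(cnt)
  if (tot <= 0) stop("GC3 undefined: no counted codons in record ",
                     record$record_id)
  sum(cnt[substr(keep, 3, 3) %in% c("G", "C")]) / tot
}

#' Usage matrix of a dataset
#'
#' Convenience layer for the analysis suite: per-record usage frequencies over
#' the 59 modelled codons, raw counts, group totals, and GC3.
#'
#' @param dataset A \code{usage_dataset}.
#' @param min_aa_count Passed to \code{\link{per_group_frequencies}}.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return List with \code{freq} (records x codons matrix, NA where a group is
#'   absent), \code{counts} (same shape, raw counts), \code{gc3} (vector) and
#'   \code{record_ids}.
#' @export
usage_matrix <- function(dataset, min_aa_count = 0L,
                         groups = build_synonym_groups()) {
  stopifnot(inherits(dataset, "usage_dataset"))
  profs <- lapply(dataset$records, per_group_frequencies,
                  min_aa_count = min_aa_count, groups = groups)
  codons <- unlist(lapply(groups, function(g) g$codons), use.names = FALSE)
  freq <- do.call(rbind, lapply(profs, function(p) p$freq[codons]))
  counts <- do.call(rbind, lapply(dataset$records,
                                  function(r) r$counts[codons]))
  ids <- unname(vapply(profs, function(p) p$record_id, ""))
  rownames(freq) <- rownames(counts) <- ids
  list(freq = freq, counts = counts,
       gc3 = setNames(vapply(profs, function(p) p$gc3, 0), ids),
       record_ids = ids)
}
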