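# Genetic code and synonymous substitution networks.

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 DNA codons in lexicographic order
#'
#' @return Character vector of the 64 codons (uppercase, DNA alphabet).
#' @export
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(DNA_BASES, DNA_BASES, paste0))),
    DNA_BASES, paste0
  )))
}

#' Retrieve a genetic code table
#'
#' Only translation tables whose codon-to-amino-acid map equals the standard
#' map are supported (NCBI tables 1 and 11): the equilibrium solutions assume
#' the standard synonym structure. Other tables are rejected rather than
#' silently mis-modelled.
#'
#' @param code_id Integer NCBI translation table identifier (1 or 11).
#' @return Object of class \code{genetic_code}: list with \code{code_id} and
#'   \code{codon_to_aa}, a named character vector over all 64 codons with
#'   \code{"*"} for stop codons.
#' @export
genetic_code <- function(code_id = 11L) {
  if (!code_id %in% c(1L, 11L)) {
    stop("unsupported genetic code table ", code_id,
         ": only tables 1 and 11 (standard codon->amino-acid map) are modelled")
  }
  map <- Biostrings::getGeneticCode(as.character(code_id))
  map <- map[order(names(map))]
  names(map) <- chartr("U", "T", names(map))
  stopifnot(length(map) == 64L, sum(map == "*") == 3L,
            map[["ATG"]] == "M", map[["TGG"]] == "W")
  structure(list(code_id = as.integer(code_id), codon_to_aa = map),
            class = "genetic_code")
}

# one- to three-letter amino acid labels used for group names
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' @keywords internal
normalize_codon <- function(codon) {
  codon <- toupper(chartr("U", "T", codon))
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  }
  codon
}

gc_count <- function(codon, positions = 1:3) {
  vapply(strsplit(codon, ""), function(b) sum(b[positions] %in% c("G", "C")),
         integer(1))
}

# all synonymous single-site substitution edges among `codons`
enumerate_edges <- function(codons) {
  from <- character(0); to <- character(0); pos <- integer(0)
  n <- length(codons)
  if (n >= 2L) {
    split_mat <- do.call(rbind, strsplit(codons, ""))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        diffs <- which(split_mat[i, ] != split_mat[j, ])
        if (length(diffs) == 1L) {
          from <- c(from, codons[i]); to <- c(to, codons[j])
          pos <- c(pos, diffs - 1L)
        }
      }
    }
  }
  data.frame(from = from, to = to, position = as.integer(pos),
             gc_delta = as.integer(gc_count(to) - gc_count(from)),
             stringsAsFactors = FALSE)
}

#' Build per-amino-acid synonym groups and substitution networks
#'
#' Partitions the sense codons into synonym groups, with serine split into its
#' two blocks that are disconnected under synonymous point mutation: Ser4
#' (TCA, TCC, TCG, TCT) and Ser2 (AGT, AGC). Each group carries its network of
#' synonymous single-site substitution edges and per-codon GC classes (the
#' number of G/C among the group's synonymously variable positions: third
#' position only, except first and third for arginine and leucine).
#'
#' @param code A \code{genetic_code} object.
#' @param include_nondegenerate If \code{TRUE}, also return the single-codon
#'   Met and Trp groups (family \code{"nondegenerate"}, no edges); these are
#'   never part of the equilibrium model.
#' @return Named list of \code{synonym_group} objects: 19 modelled groups
#'   (17 amino acids plus Ser2 and Ser4), each with fields \code{label},
#'   \code{aa}, \code{codons}, \code{edges}, \code{family}, \code{max_gc},
#'   \code{gc_class}.
#' @export
build_synonym_groups <- function(code = genetic_code(11L),
                                 include_nondegenerate = FALSE) {
  stopifnot(inherits(code, "genetic_code"))
  map <- code$codon_to_aa
  sense <- names(map)[map != "*"]
  groups <- list()
  for (aa in unique(map[sense])) {
    codons <- sort(sense[map[sense] == aa])
    if (aa == "S") {
      blocks <- list(Ser4 = codons[substr(codons, 1, 2) == "TC"],
                     Ser2 = codons[substr(codons, 1, 2) == "AG"])
    } else {
      blocks <- setNames(list(codons), AA3[[aa]])
    }
    for (label in names(blocks)) {
      cods <- blocks[[label]]
      n <- length(cods)
      family <- if (n == 1L) "nondegenerate"
        else if (n == 2L) "two_codon"
        else if (n == 3L) "isoleucine"
        else if (n == 4L) "four_codon"
        else "six_codon"
      if (family == "nondegenerate" && !include_nondegenerate) next
      var_pos <- if (family == "six_codon") c(1L, 3L) else 3L
      g <- setNames(gc_count(cods, var_pos), cods)
      groups[[label]] <- structure(
        list(label = label, aa = aa, codons = cods,
             edges = enumerate_edges(cods), family = family,
             max_gc = if (family == "six_codon") 2L else 1L,
             gc_class = g),
        class = "synonym_group")
    }
  }
  # stable, field-conventional order: alphabetical by label
  groups[order(names(groups))]
}

#' @export
print.synonym_group <- function(x, ...) {
  cat(sprintf("<synonym_group> %s (%s): %s; %d edges\n", x$label, x$family,
              paste(x$codons, collapse = " "), nrow(x$edges)))
  invisible(x)
}

#' GC class of a codon within its synonym group
#'
#' The GC class g counts G/C among the group's synonymously variable
#' positions: the third codon position for all groups except arginine and
#' leucine, where both first and third positions vary synonymously (so
#' g ranges over 0, 1, 2 -- the 0xGC, 1xGC and 2xGC classes).
#'
#' @param group A \code{synonym_group}.
#' @param codon Codon string belonging to the group.
#' @return Integer GC class.
#' @export
gc_class <- function(group, codon) {
  codon <- normalize_codon(codon)
  if (!codon %in% group$codons) {
    stop("codon ", codon, " is not in group ", group$label)
  }
  unname(group$gc_class[[codon]])
}

#' Model-predicted qualitative response of a codon's usage to GC bias
#'
#' Two- and four-codon groups (including Ser2/Ser4): linear in B. Isoleucine:
#' nonlinear but monotone. Arginine/leucine 0xGC and 2xGC codons: nonlinear
#' but monotone; their 1xGC codons: nonlinear and non-monotone (peaked).
#'
#' @param group A \code{synonym_group}.
#' @param codon Codon string in the group.
#' @return One of \code{"linear"}, \code{"nonlinear_monotone"},
#'   \code{"nonlinear_nonmonotone"}.
#' @export
predicted_response <- function(group, codon) {
  g <- gc_class(group, codon)
  switch(group$family,
    two_codon = ,
    four_codon = "linear",
    isoleucine = "nonlinear_monotone",
    six_codon = if (g == 1L) "nonlinear_nonmonotone" else "nonlinear_monotone",
    stop("codon ", codon, " (", group$label, ") is not modelled"))
}

#' Codons with model-predicted nonlinear usage
#'
#' The arginine and leucine codons (12) always qualify; isoleucine's three
#' codons also have nonlinear closed forms and are appended when
#' \code{include_ile = TRUE}.
#'
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @param include_ile Include the isoleucine codons.
#' @return Character vector of codons.
#' @export
nonlinear_codons <- function(groups = build_synonym_groups(),
                             include_ile = FALSE) {
  fams <- if (include_ile) c("six_codon", "isoleucine") else "six_codon"
  unlist(lapply(groups[vapply(groups, function(g) g$family, "") %in% fams],
                function(g) g$codons), use.names = FALSE)
}

#' Look up the synonym group containing a codon
#'
#' @param codon Codon string.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return The \code{synonym_group}, or an error for stop/Met/Trp codons.
#' @export
group_of <- function(codon, groups = build_synonym_groups()) {
  codon <- normalize_codon(codon)
  for (g in groups) if (codon %in% g$codons) return(g)
  stop("codon ", codon, " is not in any modelled synonym group")
}
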