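# Synthetic data: model-exact and multinomial-noise codon-usage panels, CDS
# emission, and Gillespie evolution of codon sequences under the CTMC.

resolve_bias_draws <- function(B, n_records) {
  check_bias(B)
  if (length(B) == 1L) return(rep(B, n_records))            # fixed
  if (length(B) == 2L && n_records != 2L) {                 # uniform(lo, hi)
    stopifnot(B[1] <= B[2])
    return(stats::runif(n_records, B[1], B[2]))
  }
  if (length(B) == n_records) return(B)                     # explicit grid
  stop("B must be a single value, a (lo, hi) pair, or one value per record")
}

#' Simulate a codon-usage panel from the equilibrium model
#'
#' Each record draws a GC bias B, then each synonym group's codon counts are
#' drawn multinomially around the closed-form equilibrium frequencies at that
#' B -- the count noise a species summary or a single gene exhibits. Optional
#' perturbations apply a relative usage shift to named codons (renormalized
#' within the group), emulating codon-specific avoidance effects.
#'
#' @param n_records Number of records (species or genes).
#' @param B Bias specification: a single value (fixed), a (lo, hi) pair
#'   (uniform draw per record), or a vector of length \code{n_records}
#'   (explicit grid).
#' @param codons_per_group Codon count drawn per synonym group: a positive
#'   integer, or \code{Inf} for the noiseless limit where counts equal the
#'   equilibrium frequencies exactly.
#' @param seed Integer seed; identical spec + seed reproduce the panel.
#' @param perturbations \code{NULL}, or data.frame with columns \code{codon}
#'   and \code{shift} (relative change, e.g. -0.3 moves 30\% of the codon's
#'   usage away before renormalization).
#' @param n_cds Nominal CDS count stored per record (metadata only).
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return A \code{usage_dataset}; provenance carries \code{true_B}.
#' @export
simulate_panel <- function(n_records, B = c(0.2, 0.8),
                           codons_per_group = 1e4, seed = 1L,
                           perturbations = NULL, n_cds = 100L,
                           groups = build_synonym_groups()) {
  stopifnot(n_records >= 1L, codons_per_group >= 0)
  if (!is.null(perturbations)) {
    stopifnot(is.data.frame(perturbations),
              all(c("codon", "shift") %in% names(perturbations)))
    perturbations$codon <- normalize_codon(perturbations$codon)
  }
  set.seed(seed)
  Bs <- resolve_bias_draws(B, n_records)
  codons <- all_codons()
  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    cnt <- setNames(numeric(64L), codons)
    for (gr in groups) {
      f <- closed_form_usage(gr, NULL, Bs[i])
      if (!is.null(perturbations)) {
        hit <- perturbations$codon %in% gr$codons
        if (any(hit)) {
          for (k in which(hit)) {
            cd <- perturbations$codon[k]
            f[cd] <- f[cd] * (1 + perturbations$shift[k])
          }
          if (any(f < 0)) {
            stop("perturbation drives a frequency below zero in group ",
                 gr$label)
          }
          f <- f / sum(f)
        }
      }
      if (is.infinite(codons_per_group)) {
        cnt[gr$codons] <- f
      } else {
        cnt[gr$codons] <- stats::rmultinom(1L, codons_per_group, f)[, 1L]
      }
    }
    records[[i]] <- codon_count_record(sprintf("sim%05d", i), cnt,
                                       name = sprintf("synthetic record %d", i),
                                       n_cds = n_cds)
  }
  usage_dataset(records, list(source = "simulate_panel", dialect = "synthetic",
                              seed = seed, true_B = Bs,
                              codons_per_group = codons_per_group))
}

#' Emit CDS FASTA whose codon tallies equal a dataset's counts
#'
#' One sequence per record: the record's codons in seeded random order, with
#' an initiation ATG prepended and a TAA stop appended (neither drawn from the
#' tallies). Reading back with \code{counts_from_cds_fasta(per_sequence =
#' TRUE, skip_start = TRUE, trim_stop = TRUE)} recovers the counts exactly.
#'
#' @param dataset A \code{usage_dataset} with integer counts.
#' @param path Output FASTA path.
#' @param seed Integer seed for the codon shuffle.
#' @return The path, invisibly.
#' @export
emit_cds_fasta <- function(dataset, path, seed = 1L) {
  set.seed(seed)
  seqs <- character(0)
  for (r in dataset$records) {
    if (any(r$counts != round(r$counts))) {
      stop("record ", r$record_id, " has non-integer counts")
    }
    body <- rep(names(r$counts), r$counts)
    if (length(body) == 0L) {
      warning("record ", r$record_id, " is empty; no sequence written")
      next
    }
    seqs[r$record_id] <- paste0("ATG", paste(sample(body), collapse = ""),
                                "TAA")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Gillespie evolution of a codon sequence under the GC-biased CTMC
#'
#' Exact event-driven stochastic simulation applying only synonymous
#' single-site substitutions at the rate-model rates. Codons evolve
#' independently (the model has no context dependence), so each position is
#' simulated by drawing exponential waiting times from its current exit rate
#' until the horizon is passed. The translated amino-acid sequence is
#' invariant by construction.
#'
#' @param sequence Character vector of sense codons (the initial state).
#' @param B GC bias.
#' @param times Increasing vector of snapshot times.
#' @param base_rate Scalar base mutation rate (free time scale).
#' @param seed Integer seed.
#' @param groups Output of \code{\link{build_synonym_groups}}.
#' @return List with \code{times}, \code{counts} (snapshots x 64 codon count
#'   matrix), and \code{final_sequence}.
#' @export
evolve_sequence <- function(sequence, B, times, base_rate = 1, seed = 1L,
                            groups = build_synonym_groups(
                              include_nondegenerate = TRUE)) {
  sequence <- normalize_codon(sequence)
  stopifnot(length(times) >= 1L, all(diff(c(0, times)) > 0), base_rate > 0)
  check_bias(B)
  set.seed(seed)
  # assign each position to its synonym group
  grp_of <- setNames(rep(names(groups),
                         vapply(groups, function(g) length(g$codons), 0L)),
                     unlist(lapply(groups, function(g) g$codons)))
  if (any(!sequence %in% names(grp_of))) {
    stop("sequence contains stop codons or codons outside the genetic code")
  }
  pos_group <- grp_of[sequence]
  state <- sequence
  codons <- all_codons()
  snap <- matrix(0, nrow = length(times), ncol = 64L,
                 dimnames = list(NULL, codons))
  t_prev <- 0
  for (s in seq_along(times)) {
    horizon <- times[s] - t_prev
    for (lab in unique(pos_group)) {
      gr <- groups[[lab]]
      if (nrow(gr$edges) == 0L) next  # Met/Trp: no synonymous moves
      Q <- build_rate_matrix(gr, rate_model(B, base_rate))
      exit <- -diag(Q)
      P <- Q; diag(P) <- 0
      P <- sweep(P, 1L, ifelse(exit > 0, exit, 1), "/")
      cumP <- t(apply(P, 1L, cumsum))
      idx <- which(pos_group == lab)
      st <- match(state[idx], gr$codons)
      tt <- numeric(length(idx))
      active <- exit[st] > 0
      while (any(active)) {
        a <- which(active)
        tt[a] <- tt[a] + stats::rexp(length(a), exit[st[a]])
        done <- tt[a] >= horizon
        active[a[done]] <- FALSE
        jmp <- a[!done]
        if (length(jmp)) {
          u <- stats::runif(length(jmp))
          st[jmp] <- 1L + rowSums(cumP[st[jmp], , drop = FALSE] < u)
        }
      }
      new_codons <- gr$codons[st]
      # synonymous-only guarantee: positions never leave their group
      stopifnot(all(new_codons %in% gr$codons))
      state[idx] <- new_codons
    }
    snap[s, ] <- as.numeric(table(factor(state, levels = codons)))
    t_prev <- times[s]
  }
  list(times = times, counts = snap, final_sequence = unname(state))
}
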