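# Shared fixtures: built once per test run.

std_groups <- build_synonym_groups()

# a named all-zero codon count vector
zero_counts <- function() setNames(numeric(64), all_codons())

# record with the given codon counts, all other codons zero
make_record <- function(id = "r1", ..., n_cds = 100L) {
  cnt <- zero_counts()
  vals <- c(...)
  cnt[names(vals)] <- vals
  codon_count_record(id, cnt, n_cds = n_cds)
}

# write a tiny spsum fixture with given n_cds values; counts are 1..64
write_spsum_fixture <- function(path, n_cds = c(100L, 60L, 12L)) {
  lines <- character(0)
  for (i in seq_along(n_cds)) {
    lines <- c(lines,
               sprintf("%d: Species %d: %d", 1000L + i, i, n_cds[i]),
               paste(seq_len(64L) + i, collapse = " "))
  }
  writeLines(lines, path)
  path
}

# model-exact panel (no count noise) over an explicit B grid
exact_panel <- function(B_grid) {
  simulate_panel(length(B_grid), B = B_grid, codons_per_group = Inf,
                 seed = 1L)
}
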