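## In-code fixtures: no data files; everything is constructed at test time.

## A deterministic pseudo-random base sequence (LCG so helper output is
## stable regardless of the session RNG state).
fixed_bases <- function(n, salt = 1L) {
  x <- integer(n)
  state <- 48271 * (salt + 7L) %% 2147483647
  for (i in seq_len(n)) {
    state <- (48271 * state) %% 2147483647
    x[i] <- state %% 4L
  }
  c("A", "C", "G", "T")[x + 1L]
}

## Synthetic ITS amplicon around a given 5.8S: ITS1 + 5.8S + ITS2.
make_amplicon <- function(ref58s, its1_len = 228L, its2_len = 247L,
                          salt = 1L) {
  c(fixed_bases(its1_len, salt), ref58s, fixed_bases(its2_len, salt + 100L))
}

study_ref58s <- function() read_its_fasta(ref_5p8s_path())[[1]]$seq

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
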