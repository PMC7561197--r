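# Shared fixtures: a default configuration and small generators used
# across the suite. Everything is built in code at test time.

cfg0 <- screen_config()

# a minimal valid well table for one primary plate
tiny_screen <- function(n_null = 20, seed = 1,
                        extra = NULL, noise_sd = 0.05) {
  classes <- c(rep("null", n_null), extra)
  genes <- effect_spec(sprintf("G%03d", seq_along(classes)), classes)
  make_screen(genes, noise_sd = noise_sd, seed = seed)
}

# brute-force seed oracle: does any guide's seed window match any family
# seed, by direct substring comparison (independent of scan_pool)
brute_force_scan <- function(duplexes, seeds, seed_start = 2, seed_len = 7) {
  hits <- integer(0)
  for (i in seq_len(nrow(duplexes))) {
    win <- substr(duplexes$antisense[i], seed_start, seed_start + seed_len - 1)
    for (s in seeds) if (identical(win, s)) { hits <- c(hits, duplexes$duplex_index[i]); break }
  }
  sort(hits)
}

random_pool <- function(gene, seed) {
  bases <- c("A", "C", "G", "U")
  set.seed(seed)
  g <- replicate(4, paste(sample(bases, 19, TRUE), collapse = ""))
  data.frame(gene = gene, duplex_index = 1:4,
             sense = vapply(g, function(x)
               as.character(Biostrings::reverseComplement(Biostrings::RNAString(x))),
               character(1), USE.NAMES = FALSE),
             antisense = g, stringsAsFactors = FALSE)
}
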