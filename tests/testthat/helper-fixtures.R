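# Small shared fixtures built in code at test time.

tinyConfig <- function(seed = 1, ...) {
  simConfig(n_patients_ibd = 3, n_controls = 2, n_genes = 200,
            n_persistent_up = 10, n_transient_up = 10, n_zotus = 60,
            cells_per_biopsy_range = c(50, 100), seed = seed, ...)
}

# one small fixture reused by read-only tests
tinyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateStudy(tinyConfig())
    cache
  }
})

# hand-built contig table rows
contigRow <- function(barcode, chain, cdr3, umis = 5, productive = TRUE) {
  data.frame(barcode = barcode, biopsy_id = "b1", chain = chain,
             cdr3_nt = cdr3, umis = umis, productive = productive,
             stringsAsFactors = FALSE)
}
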