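# shared low-level helpers (loaded first)

all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}
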