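# Builds the shipped 62-channel montage asset (positions from the
# azimuthal 10-10 scheme, Delaunay neighbour structure precomputed).
pkgload::load_all(".", quiet = TRUE)
m <- standardMontage62(neighbors = TRUE)
writeMontage(m, "inst/extdata/montage62.json",
             name = "standard-62", version = "1")
cat("edges:", sum(m@neighbors) / 2, "\n")
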