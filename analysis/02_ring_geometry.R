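#!/usr/bin/env Rscript
# Geometry of the three canonical iduronate ring forms: Cremer-Pople
# coordinates of the idealised rings and the inter-proton distances that
# make the H2-H5 NOE diagnostic of the skew-boat.

suppressPackageStartupMessages(library(puckerfit))
dir.create("results", showWarnings = FALSE)

rows <- lapply(c("1C4", "2SO", "4C1"), function(label) {
  ring <- build_ideal_ring(label)
  cp <- cremer_pople(ring)
  data.frame(
    label = label,
    Q = round(cp$Q, 3),
    theta = round(cp$theta, 1),
    phi = if (cp$phi_defined) round(cp$phi, 1) else NA,
    classified = classify_conformer(cp),
    d_H2H5 = round(interproton_distance(ring, "H2", "H5"), 2),
    d_H4H5 = round(interproton_distance(ring, "H4", "H5"), 2),
    j12_ideal = round(couplings_from_frame(ring)[["j12"]], 2)
  )
})
geom <- do.call(rbind, rows)
write.csv(geom, "results/ring_geometry.csv", row.names = FALSE)

print(geom, row.names = FALSE)
cat("\nFindings:\n")
cat(" - every idealised ring classifies back to its own label\n")
cat(sprintf(" - H2-H5 contracts to %.2f A in the 2SO skew-boat vs %.2f / %.2f A\n",
            geom$d_H2H5[geom$label == "2SO"],
            geom$d_H2H5[geom$label == "1C4"], geom$d_H2H5[geom$label == "4C1"]),
    "   in the chairs: the basis of the H2-H5/H4-H5 NOE ratio assay\n")
cat(sprintf(" - H4-H5 stays short in all forms (%.2f-%.2f A), anchoring the ratio\n",
            min(geom$d_H4H5), max(geom$d_H4H5)))
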