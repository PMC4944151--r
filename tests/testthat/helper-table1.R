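# Printed values of the published eight-hexasaccharide measurement table,
# frozen here as the expected outputs of the reporting pipeline.

table1_printed <- list(
  # integer percent columns; NA = printed as a dash
  pct = rbind(
    c(68, 32, NA), c(68, 32, NA), c(47, 53, NA), c(25, 75, NA),
    c(53, 47, NA), c(51, 49, NA), c(68, 29, 3), c(73, 19, 8)
  ),
  # parenthetical calculated couplings, one decimal
  calc = rbind(
    c(2.7, 4.1, 3.0, 2.1), c(2.7, 4.1, 3.0, 2.2),
    c(3.6, 5.5, 3.6, 2.5), c(4.5, 6.9, 4.2, 2.8),
    c(3.3, 5.1, 3.4, 2.4), c(3.4, 5.2, 3.5, 2.4),
    c(2.8, 4.1, 3.2, 2.2), c(2.7, 3.8, 3.2, 2.2)
  ),
  # "sum of square difference" column, two decimals
  rss = c(0.34, 0.34, 0.49, 1.02, 0.20, 0.19, 0.37, 0.26),
  noe = c(0.19, 0.21, 0.26, 0.34, 0.34, 0.35, 0.22, 0.19)
)

# path to a fresh file inside a test-scoped temporary directory
withr_local_file <- function(name) {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}

# random point on the 3-simplex
rand_simplex <- function() {
  x <- -log(stats::runif(3))
  x / sum(x)
}

# random 3x3 rotation matrix
rand_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(frame, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  atom_frame(frame$name, xyz, elements = frame$elem, ring = attr(frame, "ring"))
}
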