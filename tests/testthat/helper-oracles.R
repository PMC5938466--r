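# Independent oracles: deliberately implemented without the package's
# geometry primitives so they can arbitrate them.

# rotate point p about unit axis w by theta radians via unit quaternions
quat_rotate <- function(p, w, theta) {
  qmul <- function(a, b) {
    c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
      a[1] * b[2:4] + b[1] * a[2:4] +
        c(a[3] * b[4] - a[4] * b[3],
          a[4] * b[2] - a[2] * b[4],
          a[2] * b[3] - a[3] * b[2]))
  }
  q <- c(cos(theta / 2), sin(theta / 2) * w)
  qc <- c(q[1], -q[2:4])
  qmul(qmul(q, c(0, p)), qc)[2:4]
}

# full vector of pairwise inter-landmark distances of a p x 3 matrix
pairwise_dists <- function(m) as.vector(stats::dist(m))

# signed tetrahedron volume of rows i of m (handedness witness)
tetra_vol <- function(m, i) {
  det(rbind(m[i[2], ] - m[i[1], ],
            m[i[3], ] - m[i[1], ],
            m[i[4], ] - m[i[1], ]))
}

# signs of signed volumes over a deterministic sample of landmark quadruples
vol_signs <- function(m, n_quads = 20, seed = 99) {
  p <- nrow(m)
  set.seed(seed)
  quads <- replicate(n_quads, sample.int(p, 4L))
  apply(quads, 2L, function(i) sign(tetra_vol(m, i)))
}

# random proper rigid motion applied to every specimen of an array,
# built from QR (with det fix) -- independent of the package's rotations
apply_random_rigid <- function(A) {
  for (i in seq_len(dim(A)[3])) {
    qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_out)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::runif(3, -10, 10)
    A[, , i] <- sweep(matrix(A[, , i], ncol = 3) %*% t(Q), 2, shift, "+")
  }
  A
}

expect_rotation_matrix <- function(R, tol = 1e-9) {
  expect_lt(max(abs(t(R) %*% R - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}
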