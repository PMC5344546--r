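# shared test helpers: deterministic random deformations and fiber pairs

rand_defgrad <- function(mag = 0.05) {
  repeat {
    f <- diag(3) + matrix(rnorm(9, 0, mag), 3, 3)
    if (det(f) > 0.2) return(f)
  }
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

fiber_pair <- function(angle_deg = 30) {
  a <- angle_deg * pi / 180
  list(c(cos(a), 0, sin(a)), c(cos(a), 0, -sin(a)))
}

sym6_to_full <- function(s) {
  matrix(c(s[1], s[4], s[6],
           s[4], s[2], s[5],
           s[6], s[5], s[3]), 3, 3)
}

# materials list for single-region box fixtures
block_mats <- function(params) list(block = params)
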