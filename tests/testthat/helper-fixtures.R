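# shared fixtures: random admissible deformations, frames, and a small
# cached LV mesh

random_defgrad <- function(scale = 0.15, det_range = NULL) {
  repeat {
    F <- diag(3) + scale * matrix(rnorm(9), 3, 3)
    d <- det(F)
    if (d <= 0.05) next
    if (is.null(det_range)) return(F)
    # rescale to place det(F) in the requested range
    target <- runif(1, det_range[1], det_range[2])
    F <- F * (target / d)^(1 / 3)
    return(F)
  }
}

random_frame <- function() {
  fiber_frame(rnorm(3), rnorm(3))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small meshes are expensive to rebuild; cache per session
lv_coarse <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_idealized_lv(edge_length = 1.0)
    cache
  }
})

lv_desk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_idealized_lv(edge_length = 0.55)
    cache
  }
})
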