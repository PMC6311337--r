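# Shared fixtures, built once per test run.

default_pubis <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_pubis_phantom(pubis_phantom_spec())
    ph
  }
})

default_pubis_result <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      ph <- default_pubis()
      res <<- analyze_hemipelvis(ph$mesh, ph$landmarks)
    }
    res
  }
})

# apply a rigid (or reflecting) transform to a mesh + landmark pair
transform_phantom <- function(ph, R = diag(3), t = c(0, 0, 0)) {
  tf <- function(p) {
    p <- if (is.null(dim(p))) matrix(p, 1, 3) else p
    out <- sweep(p %*% t(R), 2, -t)
    if (nrow(out) == 1) as.numeric(out) else out
  }
  mesh <- surface_mesh(tf(ph$mesh$vertices), ph$mesh$faces)
  lm <- ph$landmarks
  for (nm in names(lm)) {
    lm[[nm]] <- tf(lm[[nm]])
  }
  class(lm) <- "landmark_set"
  list(mesh = mesh, landmarks = lm)
}

rotation3 <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

numeric_result_row <- function(res) {
  df <- as.data.frame(res)
  unlist(df[vapply(df, is.numeric, logical(1))])
}
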