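## Shared fixtures, memoized so expensive geometry is built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

## A straight vertical circular tube of the given radius/length built from
## stacked rings, closed by end fans; base pole at the origin.
make_tube_mesh <- function(radius = 1, length = 7, n_rings = 24, m = 32) {
  t <- 2 * pi * (seq_len(m) - 1) / m
  zs <- seq(0, length, length.out = n_rings + 2)[2:(n_rings + 1)]
  rings <- lapply(zs, function(z)
    cbind(radius * cos(t), radius * sin(t), z))
  spinemorph:::loft_rings(rings, matrix(c(0, 0, 0), 1, 3),
                          matrix(c(0, 0, length), 1, 3))
}

## Independent union-find over face adjacency (edge-sharing), used as the
## component-count oracle for validate_mesh.
uf_face_components <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- c(key(f[, 1], f[, 2]), key(f[, 2], f[, 3]), key(f[, 3], f[, 1]))
  owner <- split(rep(seq_len(m), 3), edges)
  for (fs in owner) if (length(fs) > 1)
    for (k in 2:length(fs)) union(fs[1], fs[k])
  length(unique(vapply(seq_len(m), find, integer(1))))
}

## Small deterministic synthetic population shared across cluster tests.
small_population <- function() memo("pop3", {
  sample_feature_population(3, 120, separation = 5, seed = 77)
})
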