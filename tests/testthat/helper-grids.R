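# small grid constructors used across tests

grid_of <- function(m, cell_km = 10, ...) {
  tradewind::wind_grid(m, cell_km = cell_km, ...)
}

random_grid <- function(nr, nc, cell_km = 10, na_frac = 0, min = 0, max = 1) {
  v <- matrix(stats::runif(nr * nc, min, max), nr, nc)
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  grid_of(v, cell_km)
}

# independent flood-fill components via igraph, for cross-checking the
# package's BFS labelling
igraph_regions <- function(mask_matrix) {
  nr <- nrow(mask_matrix); nc <- ncol(mask_matrix)
  cells <- which(mask_matrix)
  if (!length(cells)) return(integer(0))
  idx <- match(seq_len(nr * nc), cells)
  edges <- integer(0)
  for (cell in cells) {
    r <- (cell - 1L) %% nr + 1L
    cl <- (cell - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- cl + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      nb <- (cc - 1L) * nr + rr
      if (!is.na(idx[nb]) && nb > cell)
        edges <- c(edges, idx[cell], idx[nb])
    }
  }
  g <- igraph::make_graph(edges, n = length(cells), directed = FALSE)
  igraph::components(g)$membership
}

# 12-month constant stack from one matrix
const_stack <- function(m, cell_km = 10, species = "sp") {
  g <- grid_of(m, cell_km)
  tradewind::monthly_stack(rep(list(g), 12L), species)
}

small_scenario_config <- function(seed = 7, nrow = 48, ncol = 16) {
  tradewind::scenario_config(nrow = nrow, ncol = ncol, seed = seed)
}
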