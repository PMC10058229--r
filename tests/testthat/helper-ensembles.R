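# Ensemble fixtures built in code.

random_rotation_matrix <- function() {
  q <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_rigid <- function(coords, translation_scale = 20) {
  sweep(coords %*% random_rotation_matrix(), 2,
        stats::runif(3, -translation_scale, translation_scale), `+`)
}

# Build an ensemble_matrix from a list of L x 3 coordinate matrices
# (optionally with a list of occupied column sets).
make_ensemble <- function(coord_list, ids = NULL, occupied = NULL) {
  n <- length(coord_list)
  L <- nrow(coord_list[[1]])
  if (is.null(ids)) ids <- sprintf("e%02d", seq_len(n))
  arr <- array(NA_real_, dim = c(n, L, 3))
  mask <- matrix(FALSE, n, L)
  for (e in seq_len(n)) {
    occ <- if (is.null(occupied)) seq_len(L) else occupied[[e]]
    arr[e, occ, ] <- coord_list[[e]][occ, , drop = FALSE]
    mask[e, occ] <- TRUE
  }
  ensemble_matrix(ids, arr, mask)
}

# A non-degenerate reference fold for geometric tests.
test_fold <- function(L = 20, seed = 42) generate_base_chain(L, seed)

# Fixed-width PDB ATOM line for hand-built parser fixtures.
pdb_atom_line <- function(serial, name, alt, resn, chain, resno, icode = " ",
                          x = 0, y = 0, z = 0, occ = 1, b = 0, element = " C") {
  name4 <- paste0(" ", formatC(name, width = 3, flag = "-"))  # " CA " style
  sprintf("ATOM  %5d %4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resn, chain, resno, icode,
          x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}
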