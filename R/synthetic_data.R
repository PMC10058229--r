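#' Specification for a synthetic switch ensemble
#'
#' Describes a toy superfamily: several subfamilies sharing one fold
#' (a smooth C-alpha helix), a two-state hinge deformation tied to the
#' assembly-state label (the planted polymerization switch), a
#' family-specific deformation mode orthogonal to the hinge in 3L space,
#' isotropic per-atom Gaussian noise, family-specific alignment indels,
#' and occasional unresolved residues.  Nucleotide-state labels are
#' assigned independently of the geometry, planting the null that
#' hydrolysis state does not determine subunit conformation.
#'
#' @param n_families Number of subfamilies.
#' @param n_per_state Entries per (family, assembly state).
#' @param length Chain length L in residues (>= 8).
#' @param hinge_split Hinge position (interior column; residues after it
#'   rotate).
#' @param theta_unpolymerized,theta_polymerized Hinge angles (degrees)
#'   for the two assembly states; their difference is the switch size.
#' @param family_amplitude RMS per-atom amplitude (Angstrom) of the
#'   family-specific mode.
#' @param noise_sd Isotropic per-coordinate Gaussian noise SD (Angstrom).
#' @param missing_rate Per-residue probability of being unresolved.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_families = 3L, n_per_state = 8L, length = 60L,
                           hinge_split = 30L,
                           theta_unpolymerized = 0, theta_polymerized = 15,
                           family_amplitude = 1.0, noise_sd = 0.3,
                           missing_rate = 0.01, seed = 1L) {
  stopifnot(length >= 8L, hinge_split > 3L, hinge_split < length,
            noise_sd >= 0, missing_rate >= 0, missing_rate <= 1,
            n_families >= 1L, n_per_state >= 1L)
  structure(list(n_families = as.integer(n_families),
                 n_per_state = as.integer(n_per_state),
                 length = as.integer(length),
                 hinge_split = as.integer(hinge_split),
                 theta_unpolymerized = theta_unpolymerized,
                 theta_polymerized = theta_polymerized,
                 family_amplitude = family_amplitude,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the shared base fold
#'
#' A helical C-alpha curve with exact 3.8 Angstrom consecutive spacing
#' (helix radius 10 Angstrom), placed in a seeded random orientation.
#' Smooth and non-self-intersecting by construction.
#'
#' @param length Number of residues (>= 8).
#' @param seed Integer seed; same seed, same coordinates.
#' @return length x 3 coordinate matrix (Angstrom).
#' @export
generate_base_chain <- function(length, seed = 1L) {
  if (length < 8L) stop("chain length must be at least 8")
  set.seed(seed)
  radius <- 10
  omega <- 0.3                      # turn per residue (radians)
  rise <- sqrt(3.8^2 - (2 * radius * sin(omega / 2))^2)
  t <- seq_len(length) - 1L
  chain <- cbind(radius * cos(omega * t), radius * sin(omega * t), rise * t)
  chain <- chain %*% .random_rotation()
  unname(chain)
}

# proper random rotation from the current RNG stream
.random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Apply a hinge rotation to a chain
#'
#' Residues after `split` rotate by `angle` degrees about an axis through
#' the split residue's C-alpha, perpendicular to the local chain
#' direction there; residues up to and including `split` stay fixed.  A
#' point at distance d from the axis is displaced by `2 d sin(angle/2)`.
#'
#' @param chain L x 3 coordinate matrix.
#' @param split Interior residue index (1 < split < L).
#' @param angle Rotation in degrees.
#' @return L x 3 matrix with the hinge applied.
#' @export
apply_hinge <- function(chain, split, angle) {
  chain <- as.matrix(chain)
  L <- nrow(chain)
  if (split <= 1L || split >= L) stop("hinge split must be interior")
  pivot <- chain[split, ]
  direction <- chain[min(split + 1L, L), ] - chain[max(split - 1L, 1L), ]
  direction <- direction / sqrt(sum(direction^2))
  ref <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  axis <- c(direction[2] * ref[3] - direction[3] * ref[2],
            direction[3] * ref[1] - direction[1] * ref[3],
            direction[1] * ref[2] - direction[2] * ref[1])
  axis <- axis / sqrt(sum(axis^2))
  theta <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)  # Rodrigues
  mob <- chain[(split + 1L):L, , drop = FALSE]
  chain[(split + 1L):L, ] <-
    sweep(sweep(mob, 2, pivot) %*% t(R), 2, pivot, `+`)
  chain
}

# unit (3L) hinge-mode direction at the base fold, by finite difference
.hinge_mode <- function(base, split) {
  d <- as.vector(t(apply_hinge(base, split, 0.5) - base))
  d / sqrt(sum(d^2))
}

# smooth family mode: low-frequency sinusoids per axis, projected
# orthogonal to the hinge mode, scaled to unit per-atom RMS
.family_mode <- function(base, split) {
  L <- nrow(base)
  t <- (seq_len(L) - 1) / L
  M <- sapply(1:3, function(ax) {
    a <- stats::rnorm(3); phi <- stats::runif(3, 0, 2 * pi)
    a[1] * sin(2 * pi * t + phi[1]) + a[2] * sin(4 * pi * t + phi[2]) +
      a[3] * sin(6 * pi * t + phi[3])
  })
  v <- as.vector(t(M))
  h <- .hinge_mode(base, split)
  v <- v - sum(v * h) * h
  M <- matrix(v, ncol = 3, byrow = TRUE)
  M / sqrt(mean(rowSums(M^2)))
}

#' Generate a synthetic ensemble on disk
#'
#' Writes one C-alpha PDB file per entry, a gapped master-alignment FASTA
#' (one row per entry; family-specific two-residue deletions appear as
#' gap columns), and a manifest TSV — the exact inputs the pipeline
#' consumes.  Per entry: shared base fold, family mode displacement,
#' state-dependent hinge angle, Gaussian noise, random residue dropout,
#' and a random rigid pose.  Ligand codes (hence nucleotide state) are
#' drawn independently of the conformation.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return List: `manifest` and `alignment` paths, `dir`, `truth` data
#'   frame (entry-level ground truth: family, assembly state, hinge
#'   angle, ligand codes, dropped residues), and the column index sets
#'   `mobile_columns` (after the hinge) / `static_columns`.
#' @export
generate_ensemble <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- spec$length
  base <- generate_base_chain(L, spec$seed)  # also seeds the stream

  fam_seq <- replicate(spec$n_families,
                       paste(sample(unname(.aa3to1), L, replace = TRUE),
                             collapse = ""))
  # family-specific 2-residue deletions, kept clear of the hinge and ends
  forbidden <- c(1:3, (spec$hinge_split - 3L):(spec$hinge_split + 4L),
                 (L - 3L):L)
  candidates <- setdiff(seq_len(L - 1L), c(forbidden, forbidden - 1L))
  del_start <- candidates[unique(round(seq(1, length(candidates),
                                           length.out = spec$n_families)))]
  del_start <- rep_len(del_start, spec$n_families)
  deletions <- lapply(del_start, function(s) c(s, s + 1L))

  ligand_choices <- list("GTP", "GNP", "GDP", character(0))
  states <- c("unpolymerized", "polymerized")
  thetas <- c(unpolymerized = spec$theta_unpolymerized,
              polymerized = spec$theta_polymerized)

  manifest <- NULL
  truth <- NULL
  rows <- character(0)
  for (f in seq_len(spec$n_families)) {
    mode <- .family_mode(base, spec$hinge_split)
    seq_chars <- strsplit(fam_seq[f], "")[[1]]
    row_chars <- seq_chars
    row_chars[deletions[[f]]] <- "-"
    for (st in states) for (r in seq_len(spec$n_per_state)) {
      entry <- sprintf("fam%d_%s_%02d", f, substr(st, 1, 3), r)
      # hinge on the shared base fold so the switch is one common mode
      # across families; the family offset is added afterwards
      chain <- apply_hinge(base, spec$hinge_split, thetas[[st]]) +
        spec$family_amplitude * mode
      chain <- chain + matrix(stats::rnorm(3 * L, sd = spec$noise_sd), L, 3)
      dropped <- which(stats::runif(L) < spec$missing_rate)
      keep <- setdiff(seq_len(L), union(deletions[[f]], dropped))
      pose_R <- .random_rotation()
      pose_t <- stats::runif(3, -50, 50)
      xyz <- sweep(chain[keep, , drop = FALSE] %*% pose_R, 2, pose_t, `+`)

      path <- file.path(dir, paste0(entry, ".pdb"))
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(xyz)),
                       resno = keep,
                       resid = unname(.aa1to3[seq_chars[keep]]),
                       elety = rep("CA", length(keep)),
                       chain = rep("A", length(keep)))
      ligands <- ligand_choices[[sample.int(length(ligand_choices), 1L)]]
      resolution <- round(stats::runif(1, 1.5, 3.5), 2)
      manifest <- rbind(manifest, data.frame(
        entry_id = entry, path = basename(path), chain = "A",
        subfamily = sprintf("family%d", f),
        ligands = paste(ligands, collapse = ","),
        nucleotide_state = "", assembly_state = st,
        organism = "synthetic", resolution = resolution,
        method = "synthetic", stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        entry_id = entry, family = f, assembly_state = st,
        hinge_angle = thetas[[st]],
        ligands = paste(ligands, collapse = ","),
        n_dropped = length(dropped), stringsAsFactors = FALSE))
      rows <- c(rows, stats::setNames(paste(row_chars, collapse = ""), entry))
    }
  }

  aln_path <- file.path(dir, "master_alignment.fasta")
  writeLines(paste0(">", names(rows), "\n", unname(rows)), aln_path)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = man_path, alignment = aln_path, dir = dir, truth = truth,
       mobile_columns = (spec$hinge_split + 1L):L,
       static_columns = seq_len(spec$hinge_split),
       spec = spec)
}
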