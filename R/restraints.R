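#' Generate the restraint specification for a tension/torsion-controlled duplex
#'
#' Builds the full set of positional and NMR-style restraints needed to
#' hold a linear duplex at a set tension and supercoiling density in an MD
#' engine, mimicking a tweezers experiment in silico. For a core of
#' `core_bp` base pairs the construct is extended by `buffer_gc_bp` GC bp
#' at the "mobile end" (a stiff buffering stretch) and `fixed_gc_bp` GC bp
#' at the "fixed end", so a 300 bp core yields a 362 bp construct.
#'
#' Residue numbering: strand 1 runs 5'-3' over residues 1..N (bp i is
#' residue i, with bp 1 the mobile end), strand 2 over residues N+1..2N
#' with bp i paired to residue 2N+1-i. Reference (dummy) points A, B, E, F
#' sit on the tether axis beyond the mobile end and I, J beyond the fixed
#' end, at `ref_standoff_nm` from the terminal bp.
#'
#' The emitted records are:
#' \itemize{
#'  \item positional - O3' and O5' of both residues of the final (fixed-end)
#'    bp: 4 records;
#'  \item distance - one linear distance restraint per strand from the
#'    mobile-end terminal O5'/O3' to reference points A and B, with slope
#'    equal to `force_pN` per strand (zero force gives zero force constant
#'    but keeps the geometric records): 2 records;
#'  \item angle - theta1/theta2 confining mobile-end motion to the tether
#'    axis in y, and an equivalent pair for x: 4 records;
#'  \item psi - one excluded-volume angle restraint (lower bound 90 deg)
#'    per phosphorus atom on each strand plus one per terminal end atom:
#'    `2 N` records;
#'  \item buffer dihedral - one anti-bending dihedral per adjacent pair of
#'    complementary buffer phosphorus pairs (bp 2..buffer): `buffer_gc_bp - 1`
#'    records;
#'  \item torsion dihedral - coplanarity restraints pinning the twist at the
#'    first core bp (mobile side, planes ABF/BAE) and the next-to-last bp
#'    (fixed side, reference points I, J): 2 records.
#' }
#'
#' @param core_bp core length in bp (>= 50); ignored when `core_seq` given
#' @param force_pN tension per strand (>= 0)
#' @param sigma target supercoiling density (|sigma| <= 0.2); recorded in
#'   the torsion records' metadata (the twist itself is built into the
#'   starting structure)
#' @param buffer_gc_bp GC buffer at the mobile end (default 60)
#' @param fixed_gc_bp GC bp at the fixed end (default 2)
#' @param core_seq optional explicit core sequence (string over ACGT)
#' @param at_frac AT fraction of a randomly generated core (default 0.49)
#' @param seed seed for the random core
#' @param ref_standoff_nm distance of the reference points from the
#'   terminal bp along the tether axis
#' @return object of class `restraint_spec`: list with `sequence` (strand 1,
#'   5'-3'), `n_bp`, `records` (data.frame), `reference_points` (named
#'   coordinate rows), and the call parameters
#' @export
gen_torsion_restraints <- function(core_bp = 300, force_pN = 0.7, sigma = 0,
                                   buffer_gc_bp = 60, fixed_gc_bp = 2,
                                   core_seq = NULL, at_frac = 0.49, seed = 1,
                                   ref_standoff_nm = 2) {
  if (!is.null(core_seq)) {
    core <- .check_sequence(core_seq)
    core_bp <- length(core)
  }
  if (core_bp < 50) stop("core must be at least 50 bp", call. = FALSE)
  if (force_pN < 0) stop("force must be non-negative", call. = FALSE)
  if (abs(sigma) > 0.2) stop("|sigma| above 0.2 is outside the supported range",
                             call. = FALSE)
  if (is.null(core_seq)) {
    rng <- .seeded_rng(seed)
    core <- sample(c("A", "T", "G", "C"), core_bp, replace = TRUE,
                   prob = c(at_frac / 2, at_frac / 2,
                            (1 - at_frac) / 2, (1 - at_frac) / 2))
    rng$restore()
  }
  buffer <- rep(c("G", "C"), length.out = buffer_gc_bp)
  fixed <- rep(c("G", "C"), length.out = fixed_gc_bp)
  seq1 <- c(buffer, core, fixed)
  N <- length(seq1)

  res2 <- function(bp) 2L * N + 1L - bp   # strand-2 residue paired with bp
  rec <- function(kind, label, res, atoms, refs = "", target = NA_real_,
                  lower = NA_real_, upper = NA_real_, force_constant = NA_real_) {
    res <- c(res, rep(NA_integer_, 4 - length(res)))
    atoms <- c(atoms, rep("", 4 - length(atoms)))
    data.frame(kind = kind, label = label,
               res1 = res[1], atom1 = atoms[1], res2 = res[2], atom2 = atoms[2],
               res3 = res[3], atom3 = atoms[3], res4 = res[4], atom4 = atoms[4],
               refs = refs, target = target, lower = lower, upper = upper,
               force_constant = force_constant)
  }
  records <- list()
  push <- function(r) records[[length(records) + 1]] <<- r

  # (i) fixed-end positional restraints: O3'/O5' of both residues of bp N
  for (res in c(N, res2(N))) for (at in c("O3'", "O5'")) {
    push(rec("positional", "fixed_end_anchor", res, at,
             force_constant = 25))
  }
  # (ii) tension: linear distance restraints, one per strand, to A and B
  push(rec("distance", "tension_strand1", 1L, "O5'", refs = "A",
           target = ref_standoff_nm * 10, force_constant = force_pN))
  push(rec("distance", "tension_strand2", res2(1L), "O3'", refs = "B",
           target = ref_standoff_nm * 10, force_constant = force_pN))
  # (iii) mobile-end axial confinement: theta pairs for y and for x
  push(rec("angle", "theta1_y", c(1L), c("O5'"), refs = "A,B", target = 90,
           lower = 80, upper = 100, force_constant = 50))
  push(rec("angle", "theta2_y", c(res2(1L)), c("O3'"), refs = "B,A", target = 90,
           lower = 80, upper = 100, force_constant = 50))
  push(rec("angle", "theta1_x", c(1L), c("O5'"), refs = "E,F", target = 90,
           lower = 80, upper = 100, force_constant = 50))
  push(rec("angle", "theta2_x", c(res2(1L)), c("O3'"), refs = "F,E", target = 90,
           lower = 80, upper = 100, force_constant = 50))
  # (iv) excluded-volume psi angles: every P on both strands, plus the two
  # terminal end atoms; lower bound 90 deg
  for (res in c(2:N, (N + 2):(2 * N))) {
    push(rec("psi", "excluded_volume", res, "P", refs = "A,B",
             lower = 90, upper = 180, force_constant = 20))
  }
  push(rec("psi", "excluded_volume_end", 1L, "O5'", refs = "A,B",
           lower = 90, upper = 180, force_constant = 20))
  push(rec("psi", "excluded_volume_end", res2(1L), "O3'", refs = "A,B",
           lower = 90, upper = 180, force_constant = 20))
  # (v) buffer anti-bending dihedrals over adjacent complementary P pairs
  for (j in 2:buffer_gc_bp) {
    push(rec("dihedral", "buffer_antibend",
             c(j - 1L, j, res2(j), res2(j - 1L)), rep("P", 4),
             target = 0, lower = -10, upper = 10, force_constant = 30))
  }
  # replace the j = 2 upstream partner when bp 1 has no P (5' end)
  records[[length(records) - (buffer_gc_bp - 2)]]$atom1 <- "O5'"
  # (vi) torsional coplanarity: mobile side at the first core bp, fixed side
  # at the next-to-last bp
  push(rec("dihedral", "torsion_mobile",
           c(buffer_gc_bp + 1L, res2(buffer_gc_bp + 1L)), c("O5'", "O3'"),
           refs = "A,B;B,A(E,F planes)", target = 0, lower = -5, upper = 5,
           force_constant = 40))
  push(rec("dihedral", "torsion_fixed",
           c(N - 1L, res2(N - 1L)), c("O5'", "O3'"),
           refs = "I,J", target = 0, lower = -5, upper = 5,
           force_constant = 40))

  records <- do.call(rbind, records)
  rownames(records) <- NULL
  # structural validation: all residues resolvable against the construct
  resx <- unlist(records[paste0("res", 1:4)])
  resx <- resx[!is.na(resx)]
  stopifnot(all(resx >= 1), all(resx <= 2 * N))
  # reference point coordinates (nm), tether axis = z
  L_nm <- N * .default_rise_nm
  refpts <- rbind(A = c(0.5, 0, -ref_standoff_nm),
                  B = c(-0.5, 0, -ref_standoff_nm),
                  E = c(0, 0.5, -ref_standoff_nm),
                  F = c(0, -0.5, -ref_standoff_nm),
                  I = c(0.5, 0, L_nm + ref_standoff_nm),
                  J = c(-0.5, 0, L_nm + ref_standoff_nm))
  colnames(refpts) <- c("x_nm", "y_nm", "z_nm")
  structure(list(sequence = paste(seq1, collapse = ""), n_bp = N,
                 records = records, reference_points = refpts,
                 core_bp = core_bp, buffer_gc_bp = buffer_gc_bp,
                 fixed_gc_bp = fixed_gc_bp, force_pN = force_pN,
                 sigma = sigma),
            class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf("<restraint_spec> %d bp construct (%d core + %d buffer + %d fixed), F = %g pN, sigma = %g\n",
              x$n_bp, x$core_bp, x$buffer_gc_bp, x$fixed_gc_bp, x$force_pN, x$sigma))
  print(table(x$records$kind))
  invisible(x)
}

#' Write a restraint specification
#'
#' `write_restraints_rst` writes AMBER NMR-restraint (`&rst`) record syntax
#' with residue:atom selectors in comments; atom serial numbers (`iat`)
#' are left as residue indices and must be resolved against the built
#' topology - the file specifies the restraints, it is not a ready-to-run
#' input. `write_restraints_json` writes the same records as neutral JSON.
#'
#' @param spec a `restraint_spec`
#' @param path output file
#' @export
write_restraints_rst <- function(spec, path) {
  stopifnot(inherits(spec, "restraint_spec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# restraint specification for a %d bp duplex (sigma = %g, F = %g pN)",
            spec$n_bp, spec$sigma, spec$force_pN),
    "# iat values are residue indices; resolve to atom serials against the",
    "# built topology. Reference points (dummy atoms):",
    apply(cbind(rownames(spec$reference_points), spec$reference_points), 1,
          function(r) sprintf("#   %s at (%s, %s, %s) nm", r[1], r[2], r[3], r[4]))),
    con)
  for (i in seq_len(nrow(spec$records))) {
    r <- spec$records[i, ]
    res <- unlist(r[paste0("res", 1:4)]); at <- unlist(r[paste0("atom", 1:4)])
    sel <- !is.na(res)
    writeLines(sprintf("# %s [%s]: %s%s", r$kind, r$label,
                       paste(sprintf("%d:%s", res[sel], at[sel]), collapse = " "),
                       if (nzchar(r$refs)) paste0(" refs ", r$refs) else ""), con)
    writeLines(sprintf(" &rst iat=%s, r1=%.1f, r2=%.1f, r3=%.1f, r4=%.1f, rk2=%.2f, rk3=%.2f, &end",
                       paste(res[sel], collapse = ","),
                       if (is.na(r$lower)) -180 else r$lower - 10,
                       if (is.na(r$lower)) (if (is.na(r$target)) 0 else r$target) else r$lower,
                       if (is.na(r$upper)) (if (is.na(r$target)) 0 else r$target) else r$upper,
                       if (is.na(r$upper)) 180 else r$upper + 10,
                       if (is.na(r$force_constant)) 0 else r$force_constant,
                       if (is.na(r$force_constant)) 0 else r$force_constant), con)
  }
  invisible(path)
}

#' @rdname write_restraints_rst
#' @export
write_restraints_json <- function(spec, path) {
  stopifnot(inherits(spec, "restraint_spec"))
  jsonlite::write_json(list(sequence = spec$sequence, n_bp = spec$n_bp,
                            force_pN = spec$force_pN, sigma = spec$sigma,
                            reference_points = as.data.frame(spec$reference_points),
                            records = spec$records),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
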