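# Constrained electrostatic-potential (ESP) charge fitting.
#
# Units: positions in Angstrom, charges in e, potentials in e/Angstrom
# with a dimensionless Coulomb constant k = 1. The fit is invariant to
# any consistent unit choice; an atomic-units toggle on I/O is provided
# by `esp_unit_factor`.
#
# Equality constraints (total charge, group sums, charge equivalences)
# are imposed exactly through a KKT (Lagrange) augmented system, not by
# penalty weights: group neutrality is a hard chemical requirement of
# the forcefield conventions being emulated.

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Unit conversion factor for ESP values
#'
#' Potentials in e/Angstrom (internal) times this factor give Hartree/e
#' (atomic units), since 1 bohr = 0.529177210903 Angstrom.
#'
#' @return scalar conversion factor.
#' @export
esp_unit_factor <- function() 1 / BOHR_PER_ANGSTROM

#' Point-charge electrostatic potential on a grid
#'
#' `V(r) = k sum_i q_i / |r - r_i|` with `k = 1` in (e, Angstrom) units.
#'
#' @param positions N x 3 atom positions, Angstrom.
#' @param charges N charges, e.
#' @param grid_points M x 3 evaluation points, Angstrom.
#' @return M potential values, e/Angstrom.
#' @export
predict_esp <- function(positions, charges, grid_points) {
  A <- esp_design_matrix(positions, grid_points)
  as.numeric(A %*% charges)
}

esp_design_matrix <- function(positions, grid_points) {
  positions <- as.matrix(positions); grid_points <- as.matrix(grid_points)
  stopifnot(ncol(positions) == 3L, ncol(grid_points) == 3L)
  A <- matrix(0, nrow(grid_points), nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d <- sqrt(rowSums(sweep(grid_points, 2, positions[i, ])^2))
    if (any(d < 1e-6))
      stop("grid point coincides with atom ", i, " (distance < 1e-6 A)")
    A[, i] <- 1 / d
  }
  A
}

#' Define an ESP fitting problem
#'
#' @param atom_positions N x 3 matrix, Angstrom.
#' @param grid_points M x 3 matrix, Angstrom.
#' @param grid_esp M potential values (e/Angstrom unless converted).
#' @param total_charge required total charge, e.
#' @param neutral_groups list of atom-index vectors whose charges must
#'   sum to a target (0 unless `group_targets` says otherwise).
#' @param group_targets numeric vector of group target sums (default all
#'   0).
#' @param equivalence_sets list of atom-index vectors constrained to
#'   carry equal charge.
#' @param restraint_weight optional harmonic restraint of charges toward
#'   zero (default 0 = none).
#' @return an object of class `ESPFitProblem`.
#' @export
esp_fit_problem <- function(atom_positions, grid_points, grid_esp,
                            total_charge = 0, neutral_groups = list(),
                            group_targets = NULL,
                            equivalence_sets = list(),
                            restraint_weight = 0) {
  atom_positions <- as.matrix(atom_positions)
  grid_points <- as.matrix(grid_points)
  n <- nrow(atom_positions)
  stopifnot(length(grid_esp) == nrow(grid_points), restraint_weight >= 0)
  idx_ok <- function(g) all(g >= 1 & g <= n & g == as.integer(g))
  if (!all(vapply(neutral_groups, idx_ok, logical(1))) ||
      !all(vapply(equivalence_sets, idx_ok, logical(1))))
    stop("constraint sets contain invalid atom indices")
  if (is.null(group_targets)) group_targets <- rep(0, length(neutral_groups))
  stopifnot(length(group_targets) == length(neutral_groups))
  structure(list(atom_positions = atom_positions, grid_points = grid_points,
                 grid_esp = as.numeric(grid_esp),
                 total_charge = total_charge,
                 neutral_groups = neutral_groups,
                 group_targets = group_targets,
                 equivalence_sets = equivalence_sets,
                 restraint_weight = restraint_weight),
            class = "ESPFitProblem")
}

constraint_matrix <- function(p) {
  n <- nrow(p$atom_positions)
  rows <- list(rep(1, n))           # total charge
  d <- c(p$total_charge)
  for (k in seq_along(p$neutral_groups)) {
    r <- numeric(n); r[p$neutral_groups[[k]]] <- 1
    rows[[length(rows) + 1L]] <- r
    d <- c(d, p$group_targets[k])
  }
  for (set in p$equivalence_sets) {
    set <- sort(unique(set))
    if (length(set) < 2L) next
    for (j in seq_along(set)[-1]) {
      r <- numeric(n); r[set[1]] <- 1; r[set[j]] <- -1
      rows[[length(rows) + 1L]] <- r
      d <- c(d, 0)
    }
  }
  list(C = do.call(rbind, rows), d = d)
}

#' Fit atomic point charges to grid potentials under hard constraints
#'
#' Minimises `sum_m (V_pred(r_m) - V_m)^2 + w * sum_i q_i^2` subject to
#' the total-charge, group-sum and equivalence equality constraints,
#' solved exactly as a linearly constrained linear least-squares problem
#' via the KKT system. Redundant (consistent) constraints are tolerated;
#' inconsistent constraints or a rank-deficient design raise errors.
#'
#' @param p an [esp_fit_problem()].
#' @return an object of class `ChargeSet`: `charges` (e),
#'   `residual_rms` (potential units), `constraint_violation_max`,
#'   `objective`.
#' @export
fit_charges <- function(p) {
  stopifnot(inherits(p, "ESPFitProblem"))
  A <- esp_design_matrix(p$atom_positions, p$grid_points)
  b <- p$grid_esp
  n <- ncol(A)
  cm <- constraint_matrix(p)
  C <- cm$C; d <- cm$d
  # drop linearly dependent constraint rows (checking consistency)
  qrC <- qr(t(C))
  keep <- qrC$pivot[seq_len(qrC$rank)]
  if (qrC$rank < nrow(C)) {
    Ck <- C[keep, , drop = FALSE]; dk <- d[keep]
    # a dependent row must have a consistent target
    coef <- qr.solve(t(Ck), t(C[-keep, , drop = FALSE]))
    implied <- as.numeric(t(coef) %*% dk)
    if (any(abs(implied - d[-keep]) > 1e-9))
      stop("inconsistent equality constraints (infeasible targets)")
    C <- Ck; d <- dk
  }
  H <- 2 * (crossprod(A) + p$restraint_weight * diag(n))
  K <- rbind(cbind(H, t(C)),
             cbind(C, matrix(0, nrow(C), nrow(C))))
  rhs <- c(2 * crossprod(A, b), d)
  qrK <- qr(K)
  if (qrK$rank < ncol(K)) {
    stop("ill-posed ESP fit: design matrix rank-deficient after ",
         "constraint elimination (", ncol(K) - qrK$rank,
         " null direction(s); add grid points or constraints)")
  }
  sol <- solve(qrK, rhs)
  q <- sol[seq_len(n)]
  resid <- as.numeric(A %*% q) - b
  viol <- max(abs(as.numeric(C %*% q) - d))
  structure(list(charges = q,
                 residual_rms = sqrt(mean(resid^2)),
                 constraint_violation_max = viol,
                 objective = sum(resid^2) +
                   p$restraint_weight * sum(q^2)),
            class = "ChargeSet")
}

#' @export
print.ChargeSet <- function(x, ...) {
  cat(sprintf(
    "ChargeSet: %d charges, sum %+.6f e, residual RMS %.3g, max violation %.2g\n",
    length(x$charges), sum(x$charges), x$residual_rms,
    x$constraint_violation_max))
  invisible(x)
}

#' Redistribute boundary charge so groups hit integral targets
#'
#' When a charge set is partitioned into transferable groups for a
#' forcefield, each group must carry its declared (usually zero) total.
#' For each group the deficit relative to its target is spread uniformly
#' over the group's non-boundary atoms; boundary (link) atoms keep their
#' fitted charge. The grand total is preserved, which requires the group
#' targets plus unassigned atoms to be consistent with the original sum.
#'
#' @param charges numeric vector of fitted charges, e.
#' @param groups list of atom-index vectors.
#' @param targets numeric vector of group target sums, one per group.
#' @param boundary_atoms atom indices excluded from redistribution.
#' @return adjusted charge vector.
#' @export
split_transferable_charges <- function(charges, groups, targets,
                                       boundary_atoms = integer(0)) {
  stopifnot(length(groups) == length(targets))
  before <- sum(charges)
  adjusted <- charges
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    recv <- setdiff(g, boundary_atoms)
    if (!length(recv))
      stop("group ", k, " has no non-boundary atoms to redistribute over")
    deficit <- targets[k] - sum(adjusted[g])
    adjusted[recv] <- adjusted[recv] + deficit / length(recv)
  }
  ungrouped <- setdiff(seq_along(charges), unlist(groups))
  drift <- before - sum(adjusted)
  if (abs(drift) > 1e-12) {
    if (!length(ungrouped))
      stop("group targets change the grand total by ",
           format(-drift), " e and no ungrouped atoms can absorb it")
    adjusted[ungrouped] <- adjusted[ungrouped] + drift / length(ungrouped)
  }
  adjusted
}
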