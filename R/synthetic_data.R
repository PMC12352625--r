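# Seeded generators for idealized haem sites, trajectories, stick spectra
# and ESP fitting problems. Every generator returns its inputs' ground
# truth alongside the data so downstream modules can be checked against
# what was actually constructed. All randomness flows from the spec seed;
# identical specs give bit-identical output.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit3 <- function(v) v / sqrt(sum(v^2))

random_unit3 <- function(n = 1L) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Specification for an idealized porphyrin haem-c site
#'
#' Geometric parameters of the synthetic site. Defaults follow the
#' damage-free ferric room-temperature values for the double-crosslink
#' question: a slightly domed macrocycle with a coordinated distal water
#' at 2.11 A and an ambiguous-band CD-C2A separation.
#'
#' @param ring_radius_n circumradius of the four pyrrole N, Angstrom
#'   (default 2.05).
#' @param fe_oop signed Fe out-of-plane displacement, Angstrom; positive
#'   is toward the distal (water) side (default 0.06).
#' @param fe_his_n Fe to proximal His N distance (default 2.14).
#' @param fe_water Fe to distal water O distance, or `NA` for no water
#'   (default 2.11).
#' @param lys_nz_cha Lys NZ to meso-CHA distance (default 1.46).
#' @param lys_cd_c2a Lys CD to C2A distance; `NA` places the CD carbon at
#'   a non-bonded 3.7 A (default 1.94).
#' @param c3a_cma exocyclic C3A-CMA bond length (default 1.43).
#' @param noise_sd isotropic Gaussian positional noise per coordinate,
#'   Angstrom (default 0).
#' @param seed integer RNG seed.
#' @return a `PorphyrinSpec` list.
#' @export
porphyrin_spec <- function(ring_radius_n = 2.05, fe_oop = 0.06,
                           fe_his_n = 2.14, fe_water = 2.11,
                           lys_nz_cha = 1.46, lys_cd_c2a = 1.94,
                           c3a_cma = 1.43, noise_sd = 0, seed = 1L) {
  lens <- c(ring_radius_n = ring_radius_n, fe_his_n = fe_his_n,
            fe_water = fe_water, lys_nz_cha = lys_nz_cha,
            lys_cd_c2a = lys_cd_c2a, c3a_cma = c3a_cma)
  bad <- names(lens)[!is.na(lens) & lens <= 0]
  if (length(bad))
    stop("lengths must be positive: ", paste(bad, collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(ring_radius_n = ring_radius_n, fe_oop = fe_oop,
                 fe_his_n = fe_his_n, fe_water = fe_water,
                 lys_nz_cha = lys_nz_cha, lys_cd_c2a = lys_cd_c2a,
                 c3a_cma = c3a_cma, noise_sd = noise_sd, seed = seed),
            class = "PorphyrinSpec")
}

#' Generate an idealized haem-c site structure with ground truth
#'
#' Builds a planar D4h-like porphine macrocycle (24 core atoms) in the
#' z = 0 plane with the pyrrole nitrogens at `ring_radius_n`, places Fe on
#' the ring normal at the signed `fe_oop`, and positions the proximal His
#' nitrogen (below the plane), the distal water oxygen (above), the
#' crosslinking Lys NZ/CD/CE atoms and the exocyclic CMA carbon so each
#' requested distance is realized exactly before noise. Side chains beyond
#' the atoms the descriptors need are omitted.
#'
#' @param spec a [porphyrin_spec()].
#' @return list with `structure` (a [Structure], chain A, HEC 201) and
#'   `truth` (requested descriptor values plus the implied crosslink and
#'   bond-character classes).
#' @export
make_porphyrin <- function(spec = porphyrin_spec()) {
  stopifnot(inherits(spec, "PorphyrinSpec"))
  deg <- pi / 180
  pol <- function(r, ang_deg) c(r * cos(ang_deg * deg),
                                r * sin(ang_deg * deg), 0)
  atoms <- list()
  add <- function(name, resname, resseq, elem, pos) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, resname = resname,
                                         resseq = resseq, element = elem,
                                         pos = pos)
  }
  ring_ax <- c(A = 45, B = 135, C = 225, D = 315)
  meso <- c(CHA = 0, CHB = 90, CHC = 180, CHD = 270)
  r_n <- spec$ring_radius_n
  r_alpha <- 1.49 * r_n   # ~3.05 A at the default N radius
  r_beta <- 2.07 * r_n    # ~4.25 A
  r_meso <- 1.68 * r_n    # ~3.45 A
  for (k in names(ring_ax)) {
    ax <- ring_ax[[k]]
    add(paste0("N", k), "HEC", 201L, "N", pol(r_n, ax))
    add(paste0("C1", k), "HEC", 201L, "C", pol(r_alpha, ax - 24))
    add(paste0("C2", k), "HEC", 201L, "C", pol(r_beta, ax - 12))
    add(paste0("C3", k), "HEC", 201L, "C", pol(r_beta, ax + 12))
    add(paste0("C4", k), "HEC", 201L, "C", pol(r_alpha, ax + 24))
  }
  for (k in names(meso))
    add(k, "HEC", 201L, "C", pol(r_meso, meso[[k]]))
  c3a_pos <- pol(r_beta, ring_ax[["A"]] + 12)
  add("CMA", "HEC", 201L, "C",
      c3a_pos + spec$c3a_cma * unit3(c(c3a_pos[1:2], 0)))
  c2c_pos <- pol(r_beta, ring_ax[["C"]] - 12)
  add("CAC", "HEC", 201L, "C",
      c2c_pos + 1.50 * unit3(c(c2c_pos[1:2], 0)))
  add("CBC", "HEC", 201L, "C",
      c2c_pos + 3.00 * unit3(c(c2c_pos[1:2], 0)))
  fe_pos <- c(0, 0, spec$fe_oop)
  add("FE", "HEC", 201L, "FE", fe_pos)
  add("NE2", "HIS", 143L, "N", fe_pos - c(0, 0, spec$fe_his_n))
  if (!is.na(spec$fe_water))
    add("O", "HOH", 301L, "O", fe_pos + c(0, 0, spec$fe_water))
  cha_pos <- pol(r_meso, 0)
  c2a_pos <- pol(r_beta, ring_ax[["A"]] - 12)
  cd_sep <- if (is.na(spec$lys_cd_c2a)) 3.7 else spec$lys_cd_c2a
  nz_pos <- cha_pos + c(0, 0, spec$lys_nz_cha)
  cd_pos <- c2a_pos + c(0, 0, cd_sep)
  add("NZ", "LYS", 78L, "N", nz_pos)
  add("CD", "LYS", 78L, "C", cd_pos)
  add("CE", "LYS", 78L, "C", (nz_pos + cd_pos) / 2 + c(0, 0, 0.6))
  tab <- new_atom_table(length(atoms))
  for (i in seq_along(atoms)) {
    a <- atoms[[i]]
    tab$serial[i] <- i; tab$name[i] <- a$name; tab$altloc[i] <- ""
    tab$resname[i] <- a$resname; tab$chain[i] <- "A"
    tab$resseq[i] <- a$resseq; tab$element[i] <- a$element
    tab$occupancy[i] <- 1; tab$bfactor[i] <- 0
    tab$x[i] <- a$pos[1]; tab$y[i] <- a$pos[2]; tab$z[i] <- a$pos[3]
  }
  if (spec$noise_sd > 0) {
    tab[, c("x", "y", "z")] <- with_seed(spec$seed,
      tab[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(tab), sd = spec$noise_sd),
               ncol = 3))
  }
  s <- Structure(list(tab), source_format = "synthetic",
                 id = "synthetic-porphyrin")
  truth <- list(
    fe_his_n = spec$fe_his_n,
    fe_water = spec$fe_water,
    fe_pyr_n = stats::setNames(rep(sqrt(r_n^2 + spec$fe_oop^2), 4),
                               c("A", "B", "C", "D")),
    lys_nz_cha = spec$lys_nz_cha,
    lys_cd_c2a = cd_sep,
    c3a_cma = spec$c3a_cma,
    fe_oop = abs(spec$fe_oop), fe_oop_signed = spec$fe_oop,
    ring_rms_dev = 0,
    crosslink_class = classify_crosslink(spec$lys_nz_cha, cd_sep),
    c3a_cma_character = assign_bond_character(spec$c3a_cma))
  list(structure = s, truth = truth)
}

#' Specification for a synthetic Fe-water trajectory
#'
#' @param n_frames number of frames (>= 1).
#' @param fe_water_distribution Gaussian mixture as a list of
#'   `c(weight, mean_A, sd_A)` components; weights must sum to 1.
#'   Default: single component at 3.3 +/- 0.1 A, the non-coordinated
#'   ferrous-like distal water.
#' @param hbond_satisfied_fraction fraction of frames constructed to
#'   satisfy the water -> pyrrole-N hydrogen-bond distance criterion
#'   (default 0.5).
#' @param seed integer RNG seed.
#' @return a `TrajectorySpec` list.
#' @export
trajectory_spec <- function(n_frames = 2000L,
                            fe_water_distribution = list(c(1, 3.3, 0.1)),
                            hbond_satisfied_fraction = 0.5,
                            seed = 1L) {
  stopifnot(n_frames >= 1)
  w <- vapply(fe_water_distribution, `[[`, numeric(1), 1L)
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (hbond_satisfied_fraction < 0 || hbond_satisfied_fraction > 1)
    stop("hbond_satisfied_fraction must be in [0, 1]")
  structure(list(n_frames = as.integer(n_frames),
                 fe_water_distribution = fe_water_distribution,
                 hbond_satisfied_fraction = hbond_satisfied_fraction,
                 seed = seed),
            class = "TrajectorySpec")
}

sample_mixture <- function(n, comps) {
  w <- vapply(comps, `[[`, numeric(1), 1L)
  pick <- sample.int(length(comps), n, replace = TRUE, prob = w)
  mu <- vapply(comps, `[[`, numeric(1), 2L)
  sd <- vapply(comps, `[[`, numeric(1), 3L)
  stats::rnorm(n, mean = mu[pick], sd = sd[pick])
}

#' Generate a trajectory with controlled Fe-water statistics
#'
#' Each frame copies the topology and re-places the water oxygen nearest
#' Fe at a distance drawn from the requested Gaussian mixture, along a
#' random direction. The direction is additionally steered so that the
#' water - acceptor hydrogen-bond distance criterion holds in exactly
#' `round(fraction * n_frames)` frames (frames chosen by a seeded draw).
#'
#' @param spec a [trajectory_spec()].
#' @param topology a [Structure] containing an Fe atom and at least one
#'   water oxygen, e.g. from [make_porphyrin()].
#' @param acceptor handle of the H-bond acceptor heavy atom; default the
#'   pyrrole ring-D nitrogen (`ND`) if present, else `NA` (no H-bond
#'   steering).
#' @param criteria [hbond_criteria()] used for the steering (heavy-atom
#'   distance only).
#' @return list with `trajectory` (a [Trajectory]) and `truth`
#'   (`distances` drawn, `n_satisfied`, `water_o`, `fe`, `acceptor`).
#' @export
make_trajectory <- function(spec = trajectory_spec(),
                            topology, acceptor = NULL,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(spec, "TrajectorySpec"))
  m <- topology$models[[1]]
  fe <- which(m$element == "FE")
  if (length(fe) != 1L) stop("topology must contain exactly one Fe atom")
  wo <- water_oxygen_handles(topology)
  if (!length(wo)) stop("topology must contain at least one water oxygen")
  fepos <- atom_pos(m, fe)
  dw <- sqrt((m$x[wo] - fepos[1])^2 + (m$y[wo] - fepos[2])^2 +
             (m$z[wo] - fepos[3])^2)
  wat <- wo[which.min(dw)]
  if (is.null(acceptor)) {
    nd <- which(m$name == "ND" & m$resname %in% c("HEC", "HEM", "HEB"))
    acceptor <- if (length(nd) == 1L) nd else NA_integer_
  }
  base <- coords(m)
  with_seed(spec$seed, {
    r <- abs(sample_mixture(spec$n_frames, spec$fe_water_distribution))
    k <- round(spec$hbond_satisfied_fraction * spec$n_frames)
    sat <- rep(FALSE, spec$n_frames)
    sat[sample.int(spec$n_frames, k)] <- TRUE
    frames <- vector("list", spec$n_frames)
    acc_dir <- if (!is.na(acceptor)) unit3(base[acceptor, ] - fepos)
    for (i in seq_len(spec$n_frames)) {
      u <- NULL
      if (is.na(acceptor)) {
        u <- random_unit3()[1, ]
      } else {
        for (trial in seq_len(64L)) {
          cand <- random_unit3()[1, ]
          # keep the draw in the hemisphere matching the desired outcome
          if ((sum(cand * acc_dir) > 0) != sat[i]) cand <- -cand
          pos <- fepos + r[i] * cand
          d_acc <- sqrt(sum((pos - base[acceptor, ])^2))
          if ((d_acc <= criteria$da_max) == sat[i]) { u <- cand; break }
        }
        if (is.null(u)) u <- if (sat[i]) acc_dir else -acc_dir
      }
      f <- base
      f[wat, ] <- fepos + r[i] * u
      frames[[i]] <- f
    }
    tr <- Trajectory(topology, frames,
                     dt_label = sprintf("synthetic, %d frames",
                                        spec$n_frames))
    list(trajectory = tr,
         truth = list(distances = r, n_satisfied = k, satisfied = sat,
                      water_o = wat, fe = fe, acceptor = acceptor))
  })
}

#' Specification for a synthetic excitation stick spectrum
#'
#' @param soret_nm wavelength of the dominant (Soret-like) transition,
#'   nm.
#' @param soret_f its oscillator strength (must exceed
#'   `background_f_max`).
#' @param n_background_states number of weaker background transitions
#'   (default 20).
#' @param background_f_max upper bound of background oscillator
#'   strengths (default 0.2).
#' @param energy_range eV range the background energies are drawn from
#'   (default 2.0-5.5 eV).
#' @param redox_state `"ferric"` or `"ferrous"`.
#' @param seed integer RNG seed.
#' @return a `StickSpectrumSpec` list.
#' @export
stick_spectrum_spec <- function(soret_nm = 460, soret_f = 1.0,
                                n_background_states = 20L,
                                background_f_max = 0.2,
                                energy_range = c(2.0, 5.5),
                                redox_state = c("ferrous", "ferric"),
                                seed = 1L) {
  redox_state <- match.arg(redox_state)
  if (soret_f <= background_f_max)
    stop("soret_f must exceed background_f_max so the dominant ",
         "transition is unambiguous")
  stopifnot(soret_nm > 0, n_background_states >= 0, background_f_max >= 0)
  structure(list(soret_nm = soret_nm, soret_f = soret_f,
                 n_background_states = as.integer(n_background_states),
                 background_f_max = background_f_max,
                 energy_range = energy_range, redox_state = redox_state,
                 seed = seed),
            class = "StickSpectrumSpec")
}

#' Generate a stick spectrum with a dominant Soret-like transition
#'
#' One transition at `hc / soret_nm` with oscillator strength `soret_f`
#' plus seeded weaker background states; transitions are emitted in
#' ascending energy order. By construction
#' `assign_soret(., "max_oscillator")` recovers `soret_nm` exactly.
#'
#' @param spec a [stick_spectrum_spec()].
#' @return list with `spectrum` (a [StickSpectrum]) and `truth`
#'   (`soret_nm`, `soret_ev`, `soret_index`).
#' @export
make_stick_spectrum <- function(spec = stick_spectrum_spec()) {
  stopifnot(inherits(spec, "StickSpectrumSpec"))
  e0 <- nm_to_ev(spec$soret_nm)
  with_seed(spec$seed, {
    eb <- stats::runif(spec$n_background_states,
                       spec$energy_range[1], spec$energy_range[2])
    fb <- stats::runif(spec$n_background_states, 0, spec$background_f_max)
    e <- c(eb, e0); f <- c(fb, spec$soret_f)
    o <- order(e)
    sp <- StickSpectrum(e[o], f[o], redox_state = spec$redox_state,
                        label = sprintf("synthetic Soret %g nm",
                                        spec$soret_nm))
    list(spectrum = sp,
         truth = list(soret_nm = spec$soret_nm, soret_ev = e0,
                      soret_index = which(o == length(e))))
  })
}

#' Generate a synthetic ESP fitting problem with known charges
#'
#' Atoms are laid out on a line, ring or random cloud; the grid is built
#' from seeded points on Merz-Kollman-style shells at 1.4-2.0 times a
#' van-der-Waals-like radius around each atom, discarding points that
#' fall inside the innermost shell of any atom; the grid potential is
#' the exact point-charge potential of the true charges plus optional
#' Gaussian noise.
#'
#' @param n_atoms number of atoms.
#' @param layout `"random"`, `"line"` or `"ring"`.
#' @param true_charges generating charges (default seeded N(0, 0.3)
#'   shifted to sum to `total_charge`).
#' @param total_charge required total charge, e (default 0).
#' @param neutral_groups,group_targets,equivalence_sets constraints
#'   passed to [esp_fit_problem()]; they must be consistent with
#'   `true_charges` for exact recovery.
#' @param grid_density points drawn per shell per atom (default 40; four
#'   shells).
#' @param noise_sd Gaussian noise added to the grid potential (default
#'   0).
#' @param vdw_radius van-der-Waals-like radius, Angstrom (default 1.7).
#' @param seed integer RNG seed.
#' @return list with `problem` (an [esp_fit_problem()]) and `truth`
#'   (`charges`).
#' @export
make_esp_problem <- function(n_atoms = 5L,
                             layout = c("random", "line", "ring"),
                             true_charges = NULL, total_charge = 0,
                             neutral_groups = list(), group_targets = NULL,
                             equivalence_sets = list(),
                             grid_density = 40L, noise_sd = 0,
                             vdw_radius = 1.7, seed = 1L) {
  layout <- match.arg(layout)
  with_seed(seed, {
    pos <- switch(layout,
      line = cbind(1.5 * (seq_len(n_atoms) - 1), 0, 0),
      ring = {
        th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
        cbind(2 * cos(th), 2 * sin(th), 0)
      },
      random = {
        p <- matrix(NA_real_, n_atoms, 3)
        i <- 1L
        while (i <= n_atoms) {
          cand <- stats::runif(3, -2, 2)
          if (i == 1L ||
              min(sqrt(rowSums(sweep(p[seq_len(i - 1L), , drop = FALSE],
                                     2, cand)^2))) >= 1.0) {
            p[i, ] <- cand; i <- i + 1L
          }
        }
        p
      })
    if (is.null(true_charges)) {
      q <- stats::rnorm(n_atoms, sd = 0.3)
      q <- q - (sum(q) - total_charge) / n_atoms
      # honour declared constraints so recovery is achievable
      for (set in equivalence_sets) q[set] <- mean(q[set])
      if (length(neutral_groups)) {
        gt <- if (is.null(group_targets)) rep(0, length(neutral_groups))
              else group_targets
        for (k in seq_along(neutral_groups)) {
          g <- neutral_groups[[k]]
          q[g] <- q[g] - (sum(q[g]) - gt[k]) / length(g)
        }
        free <- setdiff(seq_len(n_atoms), unlist(neutral_groups))
        if (length(free))
          q[free] <- q[free] - (sum(q) - total_charge) / length(free)
      }
      true_charges <- q
    }
    stopifnot(length(true_charges) == n_atoms)
    if (abs(sum(true_charges) - total_charge) > 1e-9)
      stop("true_charges do not sum to total_charge")
    shells <- seq(1.4, 2.0, length.out = 4) * vdw_radius
    pts <- do.call(rbind, lapply(seq_len(n_atoms), function(i) {
      do.call(rbind, lapply(shells, function(rr) {
        u <- random_unit3(grid_density)
        sweep(rr * u, 2, pos[i, ], `+`)
      }))
    }))
    dmin <- apply(pts, 1, function(g)
      min(sqrt(rowSums(sweep(pos, 2, g)^2))))
    pts <- pts[dmin >= shells[1] - 1e-9, , drop = FALSE]
    esp <- predict_esp(pos, true_charges, pts)
    if (noise_sd > 0) esp <- esp + stats::rnorm(length(esp), sd = noise_sd)
    prob <- esp_fit_problem(pos, pts, esp, total_charge = total_charge,
                            neutral_groups = neutral_groups,
                            group_targets = group_targets,
                            equivalence_sets = equivalence_sets)
    list(problem = prob, truth = list(charges = true_charges,
                                      noise_sd = noise_sd))
  })
}
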