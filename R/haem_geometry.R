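# Haem-site descriptors, crosslink-state and bond-character calls.
#
# Descriptor conventions:
#  * Fe-OOP is the distance from Fe to the unweighted centroid of the four
#    pyrrole nitrogens (the atoms are identical, so mass weighting is a
#    no-op). The signed variant is positive when Fe sits on the distal
#    side of the N4 least-squares plane, i.e. opposite the proximal His.
#  * ring_rms_dev is the RMS deviation of the 24-atom macrocycle core from
#    its own least-squares plane, a scalar planarity measure (no
#    decomposition into ruffling/saddling modes).

#' Default crosslink / bond-character thresholds
#'
#' `bond_max` (1.80 A) is the longest heavy-atom separation still treated
#' as a covalent crosslink bond; `ambiguous_max` (2.80 A) separates the
#' ambiguous band from a clearly unbonded single-crosslink geometry.
#' For C-C bond character, lengths at or below `cc_double_max` (1.40 A)
#' are double bonds, at or above `cc_single_min` (1.48 A) single bonds,
#' and intermediate between.
#'
#' @return named list of thresholds (Angstrom).
#' @export
geometry_thresholds <- function() {
  list(bond_max = 1.80, ambiguous_max = 2.80,
       cc_double_max = 1.40, cc_single_min = 1.48)
}

fit_plane <- function(p) {
  # least-squares plane through rows of p: returns centroid + unit normal
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  if (sv$d[2] < 1e-9)
    stop("degenerate (collinear) geometry: cannot define a plane")
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Compute the haem-site descriptor set
#'
#' Produces the full descriptor vector for a mapped haem-c site: the
#' Fe-His(N) and Fe-water coordination distances, the four Fe-pyrrole-N
#' distances, the Lys NZ-CHA and Lys CD-C2A crosslink distances, the
#' exocyclic C3A-CMA bond length, the iron out-of-plane displacement
#' (unsigned and signed, distal positive), and the macrocycle RMS
#' planarity deviation; crosslink state and exocyclic bond character are
#' classified from the distances.
#'
#' @param s a [Structure] (altlocs resolved).
#' @param site a `HaemSiteMap` from [map_haem_site()].
#' @param thresholds classification thresholds, see [geometry_thresholds()].
#' @param model model index to measure (default 1).
#' @param label free-text label stored in the report.
#' @return an object of class `GeometryReport` (a named list; `fe_water`
#'   and `lys_cd_c2a` may be `NA` when the corresponding atom is absent).
#' @export
compute_descriptors <- function(s, site, thresholds = geometry_thresholds(),
                                model = 1L, label = s$id) {
  m <- s$models[[model]]
  p <- function(h) atom_pos(m, h)
  fe <- p(site$fe)
  n4 <- rbind(p(site$na), p(site$nb), p(site$nc), p(site$nd))
  pyr <- sqrt(rowSums(sweep(n4, 2, fe)^2))
  names(pyr) <- c("A", "B", "C", "D")
  pl <- fit_plane(n4)
  oop <- dist3(fe, colMeans(n4))
  s_fe <- sum((fe - pl$centroid) * pl$normal)
  s_his <- sum((p(site$his_n) - pl$centroid) * pl$normal)
  oop_signed <- if (s_fe == 0) 0 else if (sign(s_fe) != sign(s_his)) oop else -oop

  ring_rms <- NA_real_
  if (length(site$macrocycle) >= 4L) {
    mp <- coords(m, site$macrocycle)
    rpl <- fit_plane(mp)
    dev <- as.numeric(sweep(mp, 2, rpl$centroid) %*% rpl$normal)
    ring_rms <- sqrt(mean(dev^2))
  }
  fe_water <- if (is.na(site$water_o)) NA_real_ else dist3(fe, p(site$water_o))
  lys_cd_c2a <- dist3(p(site$lys_cd), p(site$c2a))
  lys_nz_cha <- dist3(p(site$lys_nz), p(site$cha))
  c3a_cma <- dist3(p(site$c3a), p(site$cma))
  rep <- list(
    fe_his_n = dist3(fe, p(site$his_n)),
    fe_water = fe_water,
    fe_pyr_n = pyr,
    fe_pyr_n_min = min(pyr), fe_pyr_n_max = max(pyr),
    lys_nz_cha = lys_nz_cha,
    lys_cd_c2a = lys_cd_c2a,
    c3a_cma = c3a_cma,
    fe_oop = oop, fe_oop_signed = oop_signed,
    ring_rms_dev = ring_rms,
    crosslink_class = classify_crosslink(lys_nz_cha, lys_cd_c2a, thresholds),
    c3a_cma_character = assign_bond_character(c3a_cma, c("C", "C"),
                                              thresholds),
    chain = site$chain, label = label)
  structure(rep, class = "GeometryReport")
}

#' @export
print.GeometryReport <- function(x, ...) {
  cat(sprintf(
    "GeometryReport '%s' (chain %s)\n  Fe-HisN %.2f  Fe-water %s  LysN-CHA %.2f  LysCD-C2A %s\n  C3A-CMA %.2f (%s)  Fe-OOP %.2f (signed %+.2f)  ring RMS %.3f\n  crosslink: %s\n",
    x$label, x$chain, x$fe_his_n,
    if (is.na(x$fe_water)) "--" else sprintf("%.2f", x$fe_water),
    x$lys_nz_cha,
    if (is.na(x$lys_cd_c2a)) "--" else sprintf("%.2f", x$lys_cd_c2a),
    x$c3a_cma, x$c3a_cma_character, x$fe_oop, x$fe_oop_signed,
    x$ring_rms_dev, x$crosslink_class))
  invisible(x)
}

#' Classify the lysine-porphyrin crosslink state
#'
#' A covalent NZ-CHA bond (length at most `bond_max`) is required for any
#' crosslink. Given that, the CD-C2A distance decides: at most `bond_max`
#' is a double crosslink (`DC`); at least `ambiguous_max` (or an absent
#' CD-C2A measurement) is a single crosslink (`SC`); in between the call
#' is `AMBIGUOUS`. Without an NZ-CHA bond the class is `NONE`.
#'
#' @param lys_nz_cha NZ-CHA distance, Angstrom.
#' @param lys_cd_c2a CD-C2A distance, Angstrom, or `NA`.
#' @param thresholds see [geometry_thresholds()].
#' @return one of `"SC"`, `"DC"`, `"AMBIGUOUS"`, `"NONE"`.
#' @export
classify_crosslink <- function(lys_nz_cha, lys_cd_c2a = NA,
                               thresholds = geometry_thresholds()) {
  if (thresholds$bond_max >= thresholds$ambiguous_max)
    stop("thresholds must satisfy bond_max < ambiguous_max")
  if (lys_nz_cha < 0 || (!is.na(lys_cd_c2a) && lys_cd_c2a < 0))
    stop("distances must be nonnegative")
  if (lys_nz_cha > thresholds$bond_max) return("NONE")
  if (is.na(lys_cd_c2a)) return("SC")
  if (lys_cd_c2a <= thresholds$bond_max) return("DC")
  if (lys_cd_c2a >= thresholds$ambiguous_max) return("SC")
  "AMBIGUOUS"
}

#' Assign bond character from a bond length
#'
#' Only C-C bonds are supported. Classification is monotone in length:
#' short bonds are `DOUBLE`, long bonds `SINGLE`, the band between the
#' cut points `INTERMEDIATE`.
#'
#' @param length bond length, Angstrom (> 0).
#' @param pair two-element character vector of element symbols.
#' @param thresholds see [geometry_thresholds()].
#' @return one of `"DOUBLE"`, `"SINGLE"`, `"INTERMEDIATE"`.
#' @export
assign_bond_character <- function(length, pair = c("C", "C"),
                                  thresholds = geometry_thresholds()) {
  if (!is.numeric(length) || length <= 0) stop("bond length must be > 0")
  if (!identical(toupper(pair), c("C", "C")))
    stop("unsupported element pair: ", paste(pair, collapse = "-"),
         " (only C-C thresholds are tabulated)")
  if (length <= thresholds$cc_double_max) "DOUBLE"
  else if (length >= thresholds$cc_single_min) "SINGLE"
  else "INTERMEDIATE"
}

#' Compare two geometry reports
#'
#' @param a,b `GeometryReport` objects with the same descriptor schema.
#' @return a data.frame of descriptor name, value in `a`, value in `b`,
#'   and the signed delta `b - a` (`NA` where either side is absent).
#' @export
compare_reports <- function(a, b) {
  keys <- c("fe_his_n", "fe_water",
            paste0("fe_pyr_n_", c("A", "B", "C", "D")),
            "lys_nz_cha", "lys_cd_c2a", "c3a_cma",
            "fe_oop", "fe_oop_signed", "ring_rms_dev")
  get1 <- function(r, k) {
    if (startsWith(k, "fe_pyr_n_")) r$fe_pyr_n[[sub("fe_pyr_n_", "", k)]]
    else r[[k]]
  }
  va <- vapply(keys, get1, numeric(1), r = a)
  vb <- vapply(keys, get1, numeric(1), r = b)
  data.frame(descriptor = keys, a = va, b = vb, delta = vb - va,
             row.names = NULL, stringsAsFactors = FALSE)
}
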