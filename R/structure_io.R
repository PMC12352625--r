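# Coordinate I/O and haem-site atom mapping.
#
# A Structure is a list of models; each model is a data.frame of atom
# records with one row per atom. Within a model (chain, resseq, name,
# altloc) is unique. Atom "handles" are integer row indices into a model
# data.frame; all models of a Structure share the same row order, so a
# handle resolved on model 1 is valid for every frame.

ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
               "element", "occupancy", "bfactor", "x", "y", "z")

new_atom_table <- function(n = 0L) {
  data.frame(serial = integer(n), name = character(n), altloc = character(n),
             resname = character(n), chain = character(n), resseq = integer(n),
             element = character(n), occupancy = numeric(n),
             bfactor = numeric(n), x = numeric(n), y = numeric(n),
             z = numeric(n), stringsAsFactors = FALSE)
}

#' Construct a Structure object
#'
#' A `Structure` holds one or more models (conformations/frames) of the
#' same set of atoms, in Angstrom coordinates.
#'
#' @param models list of atom data.frames (columns `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resseq`, `element`, `occupancy`,
#'   `bfactor`, `x`, `y`, `z`).
#' @param source_format one of `"pdb"`, `"mmcif"`, `"xyz"`, `"synthetic"`.
#' @param id free-text identifier.
#' @return an object of class `Structure`.
#' @export
Structure <- function(models, source_format = "synthetic", id = "") {
  stopifnot(is.list(models), length(models) >= 1L)
  for (m in models) {
    miss <- setdiff(ATOM_COLS, names(m))
    if (length(miss))
      stop("atom table missing columns: ", paste(miss, collapse = ", "))
    if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z)))
      stop("non-finite coordinates in atom table")
    key <- paste(m$chain, m$resseq, m$name, m$altloc)
    if (anyDuplicated(key))
      stop("duplicate (chain, resseq, name, altloc) within a model: ",
           key[anyDuplicated(key)])
  }
  structure(list(models = models, source_format = source_format, id = id),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s' [%s]: %d model(s), %d atoms\n",
              x$id, x$source_format, length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

n_models <- function(s) length(s$models)
n_atoms <- function(s) nrow(s$models[[1]])

coords <- function(model, idx = seq_len(nrow(model))) {
  as.matrix(model[idx, c("x", "y", "z"), drop = FALSE])
}

atom_pos <- function(model, i) c(model$x[i], model$y[i], model$z[i])

dist3 <- function(a, b) sqrt(sum((a - b)^2))

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
         xyz = "xyz",
         stop("cannot infer coordinate format from extension '.", ext,
              "'; pass format_hint"))
}

#' Read a coordinate file
#'
#' Reads PDB (`ATOM`/`HETATM`/`MODEL`/`ENDMDL`), mmCIF (`_atom_site` loop)
#' or multi-frame XYZ. No atoms are dropped; coordinates are in Angstrom.
#' XYZ carries no residue metadata: names are element symbols, chain `"A"`,
#' and each atom gets its own residue number.
#'
#' @param path file path.
#' @param format_hint optional `"pdb"`, `"mmcif"` or `"xyz"`; by default
#'   inferred from the file extension.
#' @return a [Structure].
#' @export
read_structure <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (is.null(format_hint)) guess_format(path) else
    match.arg(format_hint, c("pdb", "mmcif", "xyz"))
  switch(fmt,
         pdb = read_pdb(path),
         mmcif = read_mmcif(path),
         xyz = read_xyz(path))
}

strip_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

element_from_name <- function(name) {
  core <- gsub("[0-9']", "", strip_ws(name))
  if (nchar(core) == 0L) return("")
  two <- toupper(substr(core, 1, 2))
  known2 <- c("FE", "CL", "BR", "ZN", "MG", "MN", "CU", "NI", "CO", "SE", "NA")
  if (nchar(core) >= 2 && two %in% known2 && two != "NA") return(two)
  toupper(substr(core, 1, 1))
}

parse_pdb_atom_line <- function(line, lineno) {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(strip_ws(s)))
    if (is.na(v) && nzchar(strip_ws(s)))
      stop("malformed PDB ", what, " field at line ", lineno, ": '", line, "'")
    v
  }
  x <- num(substr(line, 31, 38), "x")
  y <- num(substr(line, 39, 46), "y")
  z <- num(substr(line, 47, 54), "z")
  if (anyNA(c(x, y, z)))
    stop("missing coordinate in PDB record at line ", lineno)
  occ <- num(substr(line, 55, 60), "occupancy"); if (is.na(occ)) occ <- 1
  bf <- num(substr(line, 61, 66), "bfactor"); if (is.na(bf)) bf <- 0
  elem <- strip_ws(toupper(substr(line, 77, 78)))
  name <- strip_ws(substr(line, 13, 16))
  if (!nzchar(elem)) elem <- element_from_name(name)
  serial <- suppressWarnings(as.integer(strip_ws(substr(line, 7, 11))))
  if (is.na(serial))
    stop("malformed PDB serial at line ", lineno)
  list(serial = serial, name = name,
       altloc = strip_ws(substr(line, 17, 17)),
       resname = strip_ws(substr(line, 18, 20)),
       chain = strip_ws(substr(line, 22, 22)),
       resseq = suppressWarnings(as.integer(strip_ws(substr(line, 23, 26)))),
       element = elem, occupancy = occ, bfactor = bf, x = x, y = y, z = z)
}

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  in_model <- FALSE
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      if (length(cur)) { models[[length(models) + 1L]] <- cur; cur <- list() }
      in_model <- TRUE
    } else if (strip_ws(rec) == "ENDMDL") {
      models[[length(models) + 1L]] <- cur
      cur <- list()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      cur[[length(cur) + 1L]] <- parse_pdb_atom_line(lines[i], i)
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  models <- Filter(length, models)
  if (!length(models)) stop("no ATOM/HETATM records in ", path)
  tabs <- lapply(models, function(m)
    do.call(rbind.data.frame, c(m, list(stringsAsFactors = FALSE))))
  Structure(tabs, source_format = "pdb", id = basename(path))
}

# Minimal mmCIF tokenizer: whitespace-separated, honouring single/double
# quoted tokens. Sufficient for atom_site loops.
cif_tokens <- function(line) {
  toks <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  fields <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_", lines[i])) {
      j <- i + 1L; fl <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        fl <- c(fl, strip_ws(lines[j])); j <- j + 1L
      }
      if (any(startsWith(fl, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", fl)
        while (j <= n && !grepl("^\\s*(_|loop_|#|data_)", lines[j]) &&
               nzchar(strip_ws(lines[j]))) {
          rows[[length(rows) + 1L]] <- cif_tokens(lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("no _atom_site loop found in ", path)
  bad <- which(vapply(rows, length, 1L) != length(fields))
  if (length(bad))
    stop("malformed _atom_site row ", bad[1], " in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getf <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(default, nrow(m))
  }
  mdl_raw <- getf("pdbx_PDB_model_num", default = "1")
  qmark <- function(v, default) ifelse(v %in% c(".", "?"), default, v)
  tab <- data.frame(
    serial = as.integer(qmark(getf("id", default = "0"), "0")),
    name = qmark(getf("label_atom_id", "auth_atom_id"), ""),
    altloc = qmark(getf("label_alt_id", default = ""), ""),
    resname = qmark(getf("auth_comp_id", "label_comp_id"), ""),
    chain = qmark(getf("auth_asym_id", "label_asym_id"), ""),
    resseq = as.integer(qmark(getf("auth_seq_id", "label_seq_id"), "0")),
    element = toupper(qmark(getf("type_symbol", default = ""), "")),
    occupancy = as.numeric(qmark(getf("occupancy", default = "1"), "1")),
    bfactor = as.numeric(qmark(getf("B_iso_or_equiv", default = "0"), "0")),
    x = as.numeric(m[, "Cartn_x"]),
    y = as.numeric(m[, "Cartn_y"]),
    z = as.numeric(m[, "Cartn_z"]),
    stringsAsFactors = FALSE)
  tab$element <- ifelse(nzchar(tab$element), tab$element,
                        vapply(tab$name, element_from_name, ""))
  mdl <- as.integer(qmark(mdl_raw, "1"))
  tabs <- lapply(split(seq_len(nrow(tab)), mdl), function(ix) {
    r <- tab[ix, , drop = FALSE]; rownames(r) <- NULL; r
  })
  Structure(unname(tabs), source_format = "mmcif", id = basename(path))
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines); models <- list()
  while (i <= n && nzchar(strip_ws(lines[i]))) {
    cnt <- suppressWarnings(as.integer(strip_ws(lines[i])))
    if (is.na(cnt)) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + cnt > n) stop("truncated XYZ frame starting at line ", i)
    body <- lines[(i + 2L):(i + 1L + cnt)]
    parts <- strsplit(strip_ws(body), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      stop("malformed XYZ atom row at line ", i + 1L + bad[1])
    elem <- toupper(vapply(parts, `[[`, "", 1L))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric XYZ coordinate in frame starting at line ", i)
    tab <- data.frame(serial = seq_len(cnt), name = elem,
                      altloc = "", resname = "UNK", chain = "A",
                      resseq = seq_len(cnt), element = elem,
                      occupancy = 1, bfactor = 0,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
    models[[length(models) + 1L]] <- tab
    i <- i + 2L + cnt
    while (i <= n && !nzchar(strip_ws(lines[i]))) i <- i + 1L
  }
  if (!length(models)) stop("no frames in XYZ file ", path)
  Structure(models, source_format = "xyz", id = basename(path))
}

#' Write a Structure to PDB or XYZ
#'
#' Multi-model structures are written as `MODEL`/`ENDMDL` blocks (PDB) or
#' stacked frames (XYZ).
#'
#' @param s a [Structure].
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = NULL) {
  fmt <- if (is.null(format)) guess_format(path) else
    match.arg(format, c("pdb", "xyz"))
  con <- file(path, "w"); on.exit(close(con))
  if (fmt == "pdb") {
    multi <- n_models(s) > 1L
    for (k in seq_len(n_models(s))) {
      if (multi) writeLines(sprintf("MODEL     %4d", k), con)
      m <- s$models[[k]]
      het <- m$resname %in% c("HEC", "HEM", "HEB", "HOH", "WAT", "TIP3", "UNK")
      recs <- sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(het, "HETATM", "ATOM"), m$serial,
        ifelse(nchar(m$name) < 4, paste0(" ", m$name), m$name),
        ifelse(nzchar(m$altloc), m$altloc, " "),
        m$resname, ifelse(nzchar(m$chain), m$chain, " "), m$resseq,
        m$x, m$y, m$z, m$occupancy, m$bfactor, m$element)
      writeLines(recs, con)
      if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (k in seq_len(n_models(s))) {
      m <- s$models[[k]]
      writeLines(as.character(nrow(m)), con)
      writeLines(paste0(s$id, " frame ", k), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         m$element, m$x, m$y, m$z), con)
    }
  }
  invisible(path)
}

#' Resolve alternate locations
#'
#' Keeps, for each (chain, resseq, name), the copy with the greatest
#' fractional occupancy; ties are broken by the lower B-factor, then by
#' altloc label order. Idempotent; structures without altlocs pass
#' through unchanged.
#'
#' @param s a [Structure].
#' @param policy currently only `"max_occupancy_then_min_b"`.
#' @return a [Structure] with one copy per atom and altloc labels cleared.
#' @export
resolve_altlocs <- function(s, policy = "max_occupancy_then_min_b") {
  match.arg(policy, "max_occupancy_then_min_b")
  models <- lapply(s$models, function(m) {
    key <- paste(m$chain, m$resseq, m$name, sep = "\r")
    ord <- order(key, -m$occupancy, m$bfactor, m$altloc)
    m2 <- m[ord, , drop = FALSE]
    m2 <- m2[!duplicated(paste(m2$chain, m2$resseq, m2$name, sep = "\r")), ,
             drop = FALSE]
    m2 <- m2[order(match(paste(m2$chain, m2$resseq, m2$name, sep = "\r"),
                         unique(key))), , drop = FALSE]
    m2$altloc <- ""
    rownames(m2) <- NULL
    m2
  })
  Structure(models, source_format = s$source_format, id = s$id)
}

#' Default haem-site atom naming table
#'
#' Maps the roles used by the descriptor set to PDB atom names. Override
#' entries to accommodate naming dialects of specific depositions.
#'
#' @return a named list of naming conventions and cutoffs.
#' @export
haem_naming_defaults <- function() {
  list(
    haem_resnames = c("HEC", "HEM", "HEB"),
    fe = "FE",
    pyrrole_n = c(A = "NA", B = "NB", C = "NC", D = "ND"),
    cha = "CHA", c2a = "C2A", c3a = "C3A", cma = "CMA",
    cac = "CAC", cbc = "CBC",
    water_resnames = c("HOH", "WAT", "TIP3"),
    water_cutoff = 4.0,
    his_resname = "HIS", lys_resname = "LYS",
    macrocycle = c("NA", "NB", "NC", "ND",
                   "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B",
                   "C1C", "C2C", "C3C", "C4C", "C1D", "C2D", "C3D", "C4D",
                   "CHA", "CHB", "CHC", "CHD"))
}

#' Read a site-mapping configuration file
#'
#' Accepts either a JSON document or a flat `key: value` text file (values
#' may be comma-separated lists). Unknown keys are rejected; missing keys
#' fall back to [haem_naming_defaults()].
#'
#' @param path config file path, or `NULL` for the defaults.
#' @return a naming-table list as from [haem_naming_defaults()].
#' @export
read_site_config <- function(path = NULL) {
  cfg <- haem_naming_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  user <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    kv <- txt[grepl(":", txt) & !grepl("^\\s*#", txt)]
    keys <- strip_ws(sub(":.*", "", kv))
    vals <- lapply(strsplit(strip_ws(sub("^[^:]*:", "", kv)), "\\s*,\\s*"),
                   function(v) {
                     nv <- suppressWarnings(as.numeric(v))
                     if (!anyNA(nv)) nv else v
                   })
    stats::setNames(vals, keys)
  }
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  if (!is.null(names(cfg$pyrrole_n)) && length(cfg$pyrrole_n) == 4L &&
      is.null(names(user$pyrrole_n)))
    names(cfg$pyrrole_n) <- c("A", "B", "C", "D")
  cfg
}

#' Map the atoms of a P460 haem-c site
#'
#' Resolves stable handles (row indices into the first model) for the
#' haem iron, the four pyrrole nitrogens, the meso carbon carrying the
#' lysine crosslink, the exocyclic-bond carbons, the proximal histidine
#' nitrogen, the crosslinking lysine side chain, and (optionally) the
#' distal water oxygen.
#'
#' The proximal His nitrogen is the His-residue N atom nearest Fe (not a
#' fixed name, to tolerate NE2/ND1 dialects); the crosslinking Lys is the
#' one whose NZ is nearest the CHA meso carbon; the distal water is the
#' water oxygen nearest Fe if within `config$water_cutoff` (default 4 A).
#'
#' @param s a [Structure]; altlocs should be resolved first.
#' @param chain chain identifier to search.
#' @param config naming table from [haem_naming_defaults()] or
#'   [read_site_config()].
#' @return an object of class `HaemSiteMap`: named integer handles plus
#'   `water_o` (`NA` if absent), `macrocycle` handle vector and `chain`.
#' @export
map_haem_site <- function(s, chain = "A", config = haem_naming_defaults()) {
  m <- s$models[[1]]
  if (s$source_format == "xyz" && is.null(config$xyz_index))
    stop("XYZ input has no residue metadata; supply config$xyz_index ",
         "(a named list of atom indices)")
  if (!is.null(config$xyz_index)) {
    h <- config$xyz_index
    h$water_o <- if (is.null(h$water_o)) NA_integer_ else h$water_o
    h$chain <- chain
    h$macrocycle <- if (is.null(h$macrocycle)) integer(0) else h$macrocycle
    return(structure(h, class = "HaemSiteMap"))
  }
  hrow <- which(m$chain == chain & m$resname %in% config$haem_resnames)
  if (!length(hrow))
    stop("no haem residue (", paste(config$haem_resnames, collapse = "/"),
         ") found on chain ", chain)
  hres <- unique(m$resseq[hrow])
  if (length(hres) > 1L)
    stop("ambiguous: multiple haem residues on chain ", chain, ": ",
         paste(hres, collapse = ", "))
  haem <- hrow
  pick <- function(nm, what) {
    i <- haem[m$name[haem] == nm]
    if (length(i) != 1L)
      stop("haem atom '", nm, "' (", what, ") resolves to ", length(i),
           " atoms; resolve altlocs or override the naming table")
    i
  }
  fe <- pick(config$fe, "iron")
  if (m$element[fe] != "FE") stop("atom named '", config$fe, "' is not iron")
  pn <- vapply(config$pyrrole_n, pick, 0L, what = "pyrrole N")
  if (any(m$element[pn] != "N")) stop("pyrrole atoms must be nitrogen")
  cha <- pick(config$cha, "meso carbon")
  fepos <- atom_pos(m, fe)

  nearest <- function(cand, ref) {
    if (!length(cand)) return(NA_integer_)
    d <- sqrt((m$x[cand] - ref[1])^2 + (m$y[cand] - ref[2])^2 +
              (m$z[cand] - ref[3])^2)
    cand[which.min(d)]
  }
  his_cand <- which(m$chain == chain & m$resname == config$his_resname &
                    m$element == "N" & !(m$name %in% "N"))
  his_n <- nearest(his_cand, fepos)
  if (is.na(his_n)) stop("no proximal His nitrogen found on chain ", chain)

  nz_cand <- which(m$chain == chain & m$resname == config$lys_resname &
                   m$name == "NZ")
  lys_nz <- nearest(nz_cand, atom_pos(m, cha))
  if (is.na(lys_nz)) stop("no Lys NZ found on chain ", chain)
  lys_res <- m$resseq[lys_nz]
  lys_atom <- function(nm) {
    i <- which(m$chain == chain & m$resname == config$lys_resname &
               m$resseq == lys_res & m$name == nm)
    if (length(i) != 1L) stop("Lys ", lys_res, " atom '", nm, "' unresolved")
    i
  }
  wat_cand <- which(m$resname %in% config$water_resnames &
                    m$element == "O")
  water_o <- NA_integer_
  if (length(wat_cand)) {
    wo <- nearest(wat_cand, fepos)
    if (dist3(atom_pos(m, wo), fepos) <= config$water_cutoff) water_o <- wo
  }
  mac <- haem[m$name[haem] %in% config$macrocycle]
  site <- list(fe = fe, na = pn[["A"]], nb = pn[["B"]], nc = pn[["C"]],
               nd = pn[["D"]], cha = cha,
               c2a = pick(config$c2a, "crosslink carbon"),
               c3a = pick(config$c3a, "exocyclic-bond carbon"),
               cma = pick(config$cma, "exocyclic terminal carbon"),
               cac = pick(config$cac, "thioether carbon"),
               cbc = pick(config$cbc, "thioether carbon"),
               his_n = his_n, lys_nz = lys_nz,
               lys_cd = lys_atom("CD"), lys_ce = lys_atom("CE"),
               water_o = water_o, macrocycle = mac, chain = chain)
  structure(site, class = "HaemSiteMap")
}

#' @export
print.HaemSiteMap <- function(x, ...) {
  cat(sprintf("HaemSiteMap chain %s: Fe@%d, water %s, %d macrocycle atoms\n",
              x$chain, x$fe, if (is.na(x$water_o)) "absent" else "present",
              length(x$macrocycle)))
  invisible(x)
}
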