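test_that("PDB readback returns every atom with its fields", {
  path <- tiny_water_pdb()
  s <- read_structure(path)
  expect_s3_class(s, "Structure")
  expect_length(s$models, 1)
  m <- s$models[[1]]
  expect_equal(nrow(m), 3)
  expect_equal(m$name, c("O", "H1", "H2"))
  expect_equal(m$resname, rep("HOH", 3))
  expect_equal(m$x, c(0, 0.96, -0.24), tolerance = 1e-9)
  expect_equal(m$element, c("O", "H", "H"))
})

test_that("multi-model PDB yields equal-sized models", {
  lines <- c("MODEL     1",
             pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 1, 0, 0, element = "C"),
             "ENDMDL",
             "MODEL     2",
             pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 1, element = "C"),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 1, 0, 1, element = "C"),
             "ENDMDL")
  s <- read_structure(write_tiny_pdb(lines))
  expect_length(s$models, 2)
  expect_equal(nrow(s$models[[1]]), nrow(s$models[[2]]))
  expect_equal(s$models[[2]]$z, c(1, 1))
})

test_that("PDB round trip preserves names, count and coordinates", {
  gp <- make_porphyrin(porphyrin_spec(noise_sd = 0.01, seed = 4))
  path <- tempfile(fileext = ".pdb")
  write_structure(gp$structure, path)
  s2 <- read_structure(path)
  m1 <- gp$structure$models[[1]]; m2 <- s2$models[[1]]
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$name, m1$name)
  expect_equal(m2$resname, m1$resname)
  expect_lt(max(abs(cbind(m2$x, m2$y, m2$z) - cbind(m1$x, m1$y, m1$z))),
            1e-3)
})

test_that("XYZ round trip and frame stacking work", {
  gp <- make_porphyrin(porphyrin_spec())
  path <- tempfile(fileext = ".xyz")
  s <- gp$structure
  s$models <- list(s$models[[1]], s$models[[1]])
  write_structure(s, path, format = "xyz")
  s2 <- read_structure(path)
  expect_length(s2$models, 2)
  expect_equal(s2$models[[1]]$element, s$models[[1]]$element)
  expect_equal(s2$models[[1]]$x, s$models[[1]]$x, tolerance = 1e-5)
})

test_that("mmCIF atom_site loop parses with quoting and model split", {
  cif <- c("data_test", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_PDB_model_num",
           "ATOM 1 C CA . GLY A 1 0.0 0.0 0.0 1.00 10.0 1",
           "HETATM 2 FE FE . HEC A 201 1.5 0.0 0.0 1.00 12.0 1",
           "ATOM 3 C \"CA\" . GLY A 1 0.0 0.0 1.0 1.00 10.0 2",
           "HETATM 4 FE FE . HEC A 201 1.5 0.0 1.0 1.00 12.0 2")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_length(s$models, 2)
  expect_equal(s$models[[1]]$element, c("C", "FE"))
  expect_equal(s$models[[2]]$z, c(1, 1))
})

test_that("malformed and missing files raise informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  bad <- write_tiny_pdb("ATOM      1  CA  GLY A   1        bad coordinates")
  expect_error(read_structure(bad), "line")
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "C 0 0 0"), xyz)
  expect_error(read_structure(xyz), "truncated")
})

test_that("resolve_altlocs keeps max occupancy, then min B, and is idempotent", {
  lines <- c(
    pdb_atom_line(1, "CB", "SER", "A", 5, 0, 0, 0, altloc = "A", occ = 0.6),
    pdb_atom_line(2, "CB", "SER", "A", 5, 9, 9, 9, altloc = "B", occ = 0.4),
    pdb_atom_line(3, "OG", "SER", "A", 5, 1, 0, 0, altloc = "A", occ = 0.5,
                  b = 20),
    pdb_atom_line(4, "OG", "SER", "A", 5, 8, 8, 8, altloc = "B", occ = 0.5,
                  b = 15),
    pdb_atom_line(5, "CA", "SER", "A", 5, 2, 0, 0))
  s <- resolve_altlocs(read_structure(write_tiny_pdb(lines)))
  m <- s$models[[1]]
  expect_equal(nrow(m), 3)
  expect_equal(m$x[m$name == "CB"], 0)    # occupancy 0.6 wins
  expect_equal(m$x[m$name == "OG"], 8)    # B 15 wins the occupancy tie
  s2 <- resolve_altlocs(s)
  expect_identical(s2$models[[1]], s$models[[1]])
})

test_that("altloc-free structures pass through unchanged", {
  s <- read_structure(tiny_water_pdb())
  expect_equal(resolve_altlocs(s)$models[[1]], s$models[[1]])
})

test_that("map_haem_site resolves the generator's labelled atoms", {
  gp <- make_porphyrin(porphyrin_spec())
  s <- gp$structure
  site <- map_haem_site(s)
  m <- s$models[[1]]
  expect_equal(m$name[site$fe], "FE")
  expect_equal(m$name[c(site$na, site$nb, site$nc, site$nd)],
               c("NA", "NB", "NC", "ND"))
  expect_equal(m$name[site$cha], "CHA")
  expect_equal(m$resname[site$his_n], "HIS")
  expect_equal(m$name[site$lys_nz], "NZ")
  expect_equal(m$resname[site$water_o], "HOH")
  expect_length(site$macrocycle, 24)
})

test_that("distal water selection: nearest within cutoff, absent otherwise", {
  gp <- make_porphyrin(porphyrin_spec(fe_water = 2.1))
  site <- map_haem_site(gp$structure)
  expect_false(is.na(site$water_o))

  dry <- make_porphyrin(porphyrin_spec(fe_water = NA))
  expect_true(is.na(map_haem_site(dry$structure)$water_o))

  # add a second, farther water: the 2.1 A one must win (brute force)
  s <- gp$structure
  m <- s$models[[1]]
  fe <- which(m$name == "FE")
  extra <- m[m$resname == "HOH", ][1, ]
  extra$resseq <- 302L; extra$serial <- max(m$serial) + 1L
  extra$z <- m$z[fe] + 3.0
  s2 <- Structure(list(rbind(m, extra)), "synthetic", s$id)
  site2 <- map_haem_site(s2)
  d <- sqrt((m$x[fe] - s2$models[[1]]$x)^2 + (m$y[fe] - s2$models[[1]]$y)^2 +
            (m$z[fe] - s2$models[[1]]$z)^2)
  wats <- which(s2$models[[1]]$resname == "HOH")
  expect_equal(site2$water_o, wats[which.min(d[wats])])
  expect_equal(d[site2$water_o], 2.1, tolerance = 1e-9)
})

test_that("site mapping errors: missing haem, duplicate haem, XYZ without index", {
  s <- read_structure(tiny_water_pdb())
  expect_error(map_haem_site(s), "no haem residue")
  gp <- make_porphyrin(porphyrin_spec())
  m <- gp$structure$models[[1]]
  dup <- m[m$resname == "HEC", ]
  dup$resseq <- 202L
  dup$serial <- dup$serial + 1000L
  dup$x <- dup$x + 20
  s2 <- Structure(list(rbind(m, dup)), "synthetic", "dup")
  expect_error(map_haem_site(s2), "ambiguous")
  xyz <- tempfile(fileext = ".xyz")
  write_structure(gp$structure, xyz, format = "xyz")
  expect_error(map_haem_site(read_structure(xyz)), "xyz_index")
})

test_that("site config files override the naming table", {
  cfgfile <- tempfile(fileext = ".cfg")
  writeLines(c("# custom cutoff", "water_cutoff: 2.0",
               "haem_resnames: HEC, HEM"), cfgfile)
  cfg <- read_site_config(cfgfile)
  expect_equal(cfg$water_cutoff, 2.0)
  expect_equal(cfg$haem_resnames, c("HEC", "HEM"))
  # water at 3.3 A is outside a 2.0 A cutoff
  gp <- make_porphyrin(porphyrin_spec(fe_water = 3.3))
  expect_true(is.na(map_haem_site(gp$structure, config = cfg)$water_o))
  writeLines("not_a_key: 1", cfgfile)
  expect_error(read_site_config(cfgfile), "unknown config keys")
})
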