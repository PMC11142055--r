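# Synthetic-data generators: cavity structures for the pocket geometry,
# boundary-spanning compound libraries for the property filter, and
# Hill-model colony-formation tables for the selectivity screen; plus the
# bundled printed screening tables.

#' Generate a hollow-shell test structure with controllable openings
#'
#' Places pseudo-atoms quasi-uniformly (Fibonacci lattice) on a sphere,
#' optionally carves one or two circular openings, and perturbs positions
#' with seeded noise so the Delaunay construction is free of exact
#' cosphericity.  Atom centers sit at
#' `interior_radius + r_vdw(element) + probe_radius`, so the enclosed
#' probe-accessible void is analytically a ball of radius `interior_radius`
#' (volume 4/3 pi r^3), the oracle used in the geometry tests.
#'
#' @param interior_radius Radius of the probe-accessible interior void,
#'   Angstrom (default 6).
#' @param opening_half_angles Numeric vector of cap half-angles in degrees;
#'   one entry per opening (first about +z, second about -z).  Empty vector
#'   or 0 gives a closed shell (an interior void with no mouth).
#' @param atom_spacing Approximate inter-atom spacing on the shell, Angstrom.
#' @param element Element symbol for the pseudo-atoms (sets the vdW radius).
#' @param probe_radius Probe radius the geometry will be analysed with.
#' @param lining Residue names assigned cyclically to atoms (controls the
#'   pocket's polar-residue count).
#' @param jitter Positional noise amplitude, Angstrom.
#' @param seed RNG seed; generation is byte-deterministic given the seed.
#' @param path Optional path to also write the structure as a PDB file.
#' @return A `structure3d`; attributes `interior_radius`, `shell_radius`,
#'   `analytic_void_volume`.
#' @export
make_cavity_structure <- function(interior_radius = 6,
                                  opening_half_angles = 30,
                                  atom_spacing = 2.0, element = "C",
                                  probe_radius = 1.4,
                                  lining = c("SER", "SER", "LEU"),
                                  jitter = 0.12, seed = 1, path = NULL) {
  stopifnot(interior_radius > 0, atom_spacing > 0, jitter >= 0)
  opening_half_angles <- opening_half_angles[opening_half_angles > 0]
  if (length(opening_half_angles) > 2) {
    stop("at most two openings (antipodal caps) are supported")
  }
  r_atom <- unname(bondi_radii()[element])
  if (is.na(r_atom)) stop("unknown element for cavity shell: ", element)
  shell_radius <- interior_radius + r_atom + probe_radius
  n <- round(4 * pi * shell_radius^2 / atom_spacing^2)
  if (n < 30) stop("atom_spacing too coarse to close the shell")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- acos(pmin(pmax(z, -1), 1))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  keep <- rep(TRUE, n)
  if (length(opening_half_angles) >= 1) {
    keep <- keep & (theta > opening_half_angles[1] * pi / 180)
  }
  if (length(opening_half_angles) == 2) {
    keep <- keep & ((pi - theta) > opening_half_angles[2] * pi / 180)
  }
  theta <- theta[keep]; phi <- phi[keep]
  m <- length(theta)
  xyz <- with_seed(seed, {
    pts <- shell_radius * cbind(sin(theta) * cos(phi),
                                sin(theta) * sin(phi),
                                cos(theta))
    pts + matrix(stats::runif(3 * m, -jitter, jitter), m, 3)
  })
  atoms <- data.frame(
    serial = seq_len(m), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = r_atom,
    residue_name = rep_len(lining, m),
    residue_seq = seq_len(m), chain_id = "A",
    is_heteroatom = FALSE,
    atom_name = element,
    stringsAsFactors = FALSE
  )
  s <- new_structure(atoms, id = sprintf("cavity_r%g_seed%d", interior_radius, seed))
  attr(s, "interior_radius") <- interior_radius
  attr(s, "shell_radius") <- shell_radius
  attr(s, "analytic_void_volume") <- 4 / 3 * pi * interior_radius^3
  if (!is.null(path)) write_structure(s, path)
  s
}

#' Generate a compound library spanning the drug-likeness filter boundaries
#'
#' Deterministic SMILES library in which every compound is annotated with
#' the verdict the property filter should reach and why: in-range alkanes
#' and alcohols (pass), short alkanes below the 160 g/mol bound (ethanol is
#' always included), long alkanes above 480 g/mol, oligoglycines with
#' TPSA >= 140, polyols with >= 5 H-bond donors, and methyl-capped
#' polyethers with >= 10 acceptors.
#'
#' @param n Library size (>= 10).
#' @param seed RNG seed (orders the library deterministically).
#' @param path Optional path to write a .smi file (SMILES TAB id).
#' @return Data frame: compound_id, smiles, class, intended_pass,
#'   intended_reasons (comma-joined, "" when passing).
#' @export
make_compound_library <- function(n = 250, seed = 7, path = NULL) {
  stopifnot(n >= 10)
  alkane <- function(k) strrep("C", k)
  alcohol <- function(k) paste0("O", strrep("C", k))
  oligoglycine <- function(m) paste0("NCC(=O)", strrep("NCC(=O)", m - 2), "NCC(=O)O")
  rows <- list()
  add <- function(smiles, class, pass, reasons) {
    rows[[length(rows) + 1]] <<- data.frame(
      smiles = smiles, class = class, intended_pass = pass,
      intended_reasons = reasons, stringsAsFactors = FALSE)
  }
  n_pass <- ceiling(0.4 * n)
  n_low <- ceiling(0.2 * n)
  n_high <- ceiling(0.15 * n)
  n_tpsa <- ceiling(0.10 * n)
  n_hbd <- ceiling(0.075 * n)
  n_hba <- n - n_pass - n_low - n_high - n_tpsa - n_hbd
  ks <- rep_len(12:30, n_pass)
  for (j in seq_len(n_pass)) {
    if (j %% 2 == 1) add(alkane(ks[j]), "pass_alkane", TRUE, "")
    else add(alcohol(ks[j]), "pass_alcohol", TRUE, "")
  }
  add("CCO", "fail_mw_low", FALSE, "mw")   # ethanol control, 46.07 g/mol
  ks <- rep_len(3:10, max(n_low - 1, 0))
  for (k in ks) add(alkane(k), "fail_mw_low", FALSE, "mw")
  ks <- rep_len(36:44, n_high)
  for (k in ks) add(alkane(k), "fail_mw_high", FALSE, "mw")
  ms <- rep_len(5:8, n_tpsa)
  for (m in ms) add(oligoglycine(m), "fail_tpsa", FALSE, "tpsa")
  hbd_ex <- c("OCC(O)C(O)C(O)C(O)CO",   # hexitol: 6 donors, TPSA 121
              "CC(O)C(O)C(O)C(O)CO")    # deoxyhexitol: 5 donors
  for (j in seq_len(n_hbd)) add(hbd_ex[(j - 1) %% 2 + 1], "fail_hbd", FALSE, "hbd")
  hba_ex <- c(paste0("CO", strrep("CCO", 9), "C"),        # PEG ether, 10 O
              paste0("CC(C)O", strrep("CCO", 9), "C"))
  for (j in seq_len(max(n_hba, 1))) add(hba_ex[(j - 1) %% 2 + 1], "fail_hba", FALSE, "hba")
  lib <- do.call(rbind, rows)
  lib <- with_seed(seed, lib[sample.int(nrow(lib)), , drop = FALSE])
  lib <- lib[seq_len(n), , drop = FALSE]
  lib$compound_id <- sprintf("CMP-%03d", seq_len(nrow(lib)))
  rownames(lib) <- NULL
  lib <- lib[, c("compound_id", "smiles", "class", "intended_pass",
                 "intended_reasons")]
  if (!is.null(path)) {
    writeLines(paste(lib$smiles, lib$compound_id, sep = "\t"), path)
  }
  lib
}

#' Build a simulation design for the selectivity screen
#'
#' Defines sites, compounds, cell lines and per-(compound, cell line) Hill
#' dose-response parameters.  Compounds at the planted selective site(s)
#' get potent cancer-cell inhibition (sub-micromolar half-maximal
#' concentration) with inert bone-marrow response; other compounds are
#' either inert everywhere or equitoxic (same potency on marrow as cancer
#' cells), so their efficacy ratios sit near 1.
#'
#' @param sites Site names; the first is the planted selective site.
#' @param compounds_per_site Compounds per site.
#' @param n_selective How many compounds at the selective site are truly
#'   selective.
#' @param cell_lines Cancer cell-line names.
#' @param concentrations Tested concentrations, micromolar.
#' @param noise_sd Truncated-Gaussian noise on percent-of-control.
#' @param replicates Wells per condition (>= 2).
#' @param seed RNG seed.
#' @return A `colony_sim_spec` list.
#' @export
colony_sim_spec <- function(sites = c("SiteA", "SiteB", "SiteC", "SiteD"),
                            compounds_per_site = 5, n_selective = 3,
                            cell_lines = c("HT116", "HT29", "MCF-7",
                                           "MDAMB231", "H226", "A549",
                                           "PC3-M", "LNCaP"),
                            concentrations = c(0.017, 0.12, 0.82, 5.7, 40),
                            noise_sd = 5, replicates = 2, seed = 1) {
  stopifnot(replicates >= 2, noise_sd >= 0, n_selective <= compounds_per_site)
  compounds <- expand.grid(idx = seq_len(compounds_per_site), site = sites,
                           stringsAsFactors = FALSE)
  compounds$compound_id <- sprintf("%s-%03d", compounds$site, compounds$idx)
  with_seed(seed, {
    eff <- list()
    marrow <- list()
    for (i in seq_len(nrow(compounds))) {
      cid <- compounds$compound_id[i]
      selective <- compounds$site[i] == sites[1] &&
        compounds$idx[i] <= n_selective
      equitoxic <- !selective && stats::runif(1) < 0.3
      for (cl in cell_lines) {
        ic50 <- if (selective) stats::runif(1, 0.05, 1)
        else if (equitoxic) stats::runif(1, 1, 10)
        else stats::runif(1, 2000, 5000)          # inert in tested range
        eff[[length(eff) + 1]] <- data.frame(
          compound_id = cid, cell_line = cl, ic50 = ic50,
          hill = stats::runif(1, 1, 2),
          emax = if (selective) stats::runif(1, 0.85, 1)
          else if (equitoxic) stats::runif(1, 0.4, 0.6) else 0.2,
          stringsAsFactors = FALSE)
      }
      # equitoxic compounds inhibit marrow as much as cancer cells, so
      # their efficacy ratios stay near 1
      marrow[[length(marrow) + 1]] <- data.frame(
        compound_id = cid,
        ic50 = if (equitoxic) stats::runif(1, 1, 10) else stats::runif(1, 2000, 5000),
        hill = stats::runif(1, 1, 2),
        emax = if (equitoxic) stats::runif(1, 0.4, 0.6) else 0.15,
        recovery = stats::runif(1, 0.5, 1),       # day-14 rebound fraction
        stringsAsFactors = FALSE)
    }
    structure(list(
      sites = sites, selective_site = sites[1],
      compounds = compounds[, c("compound_id", "site")],
      cell_lines = cell_lines, concentrations = concentrations,
      effect = do.call(rbind, eff), marrow_effect = do.call(rbind, marrow),
      noise_sd = noise_sd, replicates = replicates, seed = seed
    ), class = "colony_sim_spec")
  })
}

hill_percent <- function(conc, ic50, hill, emax) {
  100 * (1 - emax * conc^hill / (conc^hill + ic50^hill))
}

#' Simulate a colony-formation measurement table
#'
#' Draws percent-of-control values from the spec's Hill means with
#' truncated Gaussian noise (never below 0), `replicates` wells per
#' condition.  Cancer cell lines are measured at day 8; bone marrow at day
#' 8 and day 14, the latter with a per-compound recovery multiplier.
#'
#' @param spec A `colony_sim_spec`.
#' @param path Optional CSV output path.
#' @return Data frame of colony measurements (columns compound_id,
#'   target_site, cell_line, concentration, percent_of_control,
#'   timepoint_days, replicate); ground-truth parameters in attribute
#'   `truth`.
#' @export
make_colony_table <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "colony_sim_spec"))
  site_of <- stats::setNames(spec$compounds$site, spec$compounds$compound_id)
  rows <- list()
  with_seed(spec$seed + 104729L, {
    for (i in seq_len(nrow(spec$effect))) {
      e <- spec$effect[i, ]
      for (conc in spec$concentrations) {
        mu <- hill_percent(conc, e$ic50, e$hill, e$emax)
        val <- pmax(mu + stats::rnorm(spec$replicates, 0, spec$noise_sd), 0)
        rows[[length(rows) + 1]] <- data.frame(
          compound_id = e$compound_id,
          target_site = unname(site_of[e$compound_id]),
          cell_line = e$cell_line, concentration = conc,
          percent_of_control = val, timepoint_days = 8,
          replicate = seq_len(spec$replicates), stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(spec$marrow_effect))) {
      e <- spec$marrow_effect[i, ]
      for (conc in spec$concentrations) {
        mu8 <- hill_percent(conc, e$ic50, e$hill, e$emax)
        mu14 <- 100 - (100 - mu8) * (1 - e$recovery)
        for (tp in c(8, 14)) {
          mu <- if (tp == 8) mu8 else mu14
          val <- pmax(mu + stats::rnorm(spec$replicates, 0, spec$noise_sd), 0)
          rows[[length(rows) + 1]] <- data.frame(
            compound_id = e$compound_id,
            target_site = unname(site_of[e$compound_id]),
            cell_line = "bone_marrow", concentration = conc,
            percent_of_control = val, timepoint_days = tp,
            replicate = seq_len(spec$replicates), stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- spec
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Load the bundled printed screening tables
#'
#' Returns the three published screening tables shipped with the package,
#' transcribed exactly as printed: bone-marrow colony formation at 40 uM
#' (day 8 / day 14, 38 compounds), the 40 uM efficacy-ratio table and the
#' 5.7 uM efficacy-ratio table.  Untested entries are printed "-" and parse
#' to NA; the "HT116" cell-line spelling is kept verbatim.  File integrity
#' is checked against vendored md5 sums.
#'
#' @return List with `table1` (compound, site, day8, day14), `table2` and
#'   `table4` (long efficacy tables: compound_id, site, cell_line,
#'   concentration, ratio).
#' @export
bundled_tables <- function() {
  dir <- system.file("extdata", package = "pocketscreen")
  files <- c("table1.csv", "table2.csv", "table4.csv")
  paths <- file.path(dir, files)
  names(paths) <- files
  sums <- tools::md5sum(paths)
  names(sums) <- files
  expected <- c(
    table1.csv = "1c321904cdbaf4058d0d298eef826bda",
    table2.csv = "0ec8539bb0a860b4c4d0a9f44c18e046",
    table4.csv = "9384729d549a83d2448e78fbc534ec8f"
  )
  bad <- names(expected)[unname(sums[names(expected)]) != expected]
  if (length(bad) > 0) {
    stop("bundled table integrity check failed for: ",
         paste(bad, collapse = ", "))
  }
  t1 <- utils::read.csv(paths["table1.csv"], stringsAsFactors = FALSE)
  parse_ratios <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(ratio = "character"))
    d$ratio <- suppressWarnings(as.numeric(ifelse(d$ratio == "-", NA, d$ratio)))
    d
  }
  list(table1 = t1,
       table2 = parse_ratios(paths["table2.csv"]),
       table4 = parse_ratios(paths["table4.csv"]))
}
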