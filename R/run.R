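# Pipeline orchestration: validated run configuration, stage functions
# (prepare / charges / spectrum / scan / compare / fixtures) with file
# handoffs through an output directory, and reproducible run manifests.
# The thin command-line dispatcher in inst/cli/phycospec.R calls these.

.config_schema <- list(
  top = c("output_dir", "seed", "parameters", "structure", "chromophore",
          "charges", "spectrum", "ci", "scan", "compare"),
  structure = c("pdb", "fixture"),
  fixture = c("kind", "n_conjugated", "protonated", "n_waters", "r_min",
              "r_max"),
  chromophore = c("id", "chain", "resno", "ring_nitrogens", "linkage"),
  charges = c("engine", "chains", "counter_ion_seed"),
  spectrum = c("radius", "environment"),
  ci = c("n_singles", "include_paired_doubles"),
  scan = c("radii", "exclusions", "label"),
  compare = c("models"))

#' Load and validate a run configuration
#'
#' Accepts a YAML file path or a plain list; unknown keys are rejected
#' before any computation starts.
#'
#' @param config path to a YAML configuration or a named list.
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
    cfg$.source <- normalizePath(config)
  } else {
    cfg <- config
  }
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), c(allowed, ".source"))
    if (length(extra)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  check_keys(cfg, .config_schema$top, "top level")
  for (sec in c("structure", "chromophore", "charges", "spectrum", "ci",
                "scan", "compare")) {
    if (!is.null(cfg[[sec]])) {
      check_keys(cfg[[sec]], .config_schema[[sec]], sec)
    }
  }
  if (!is.null(cfg$structure$fixture)) {
    check_keys(cfg$structure$fixture, .config_schema$fixture,
               "structure$fixture")
  }
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' @keywords internal
config_params <- function(cfg) {
  if (is.null(cfg$parameters)) indo_params() else indo_params(cfg$parameters)
}

#' @keywords internal
config_chromophore_spec <- function(cfg) {
  ch <- cfg$chromophore
  if (is.null(ch)) {
    return(chromophore_spec("surrogate"))
  }
  chromophore_spec(ch$id %||% "chromophore",
                   chain_id = ch$chain %||% "X",
                   residue_number = ch$resno %||% 1L,
                   ring_nitrogens = ch$ring_nitrogens %||%
                     list(B = "NB", C = "NC"),
                   linkage = ch$linkage)
}

# Write a stage manifest: config hash, input checksums, seeds, versions.
#' @keywords internal
write_manifest <- function(cfg, stage, inputs, outputs) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(cfg)
  cfg_plain$.source <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg_plain), tmp)
  manifest <- list(
    stage = stage,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("phycospec")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = lapply(Filter(function(f) isTRUE(file.exists(f)), inputs),
                    function(f) unname(tools::md5sum(f))),
    outputs = lapply(Filter(function(f) isTRUE(file.exists(f)), outputs),
                     function(f) unname(tools::md5sum(f))))
  path <- file.path(cfg$output_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @keywords internal
stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' @keywords internal
load_structure <- function(cfg) {
  st <- cfg$structure
  if (!is.null(st$pdb)) return(read_pdb(st$pdb))
  fx <- st$fixture
  if (is.null(fx)) stop("config needs structure$pdb or structure$fixture")
  if (identical(fx$kind, "pcb_surrogate")) {
    s <- make_pcb_surrogate(fx$n_conjugated %||% 2,
                            protonated = fx$protonated %||% TRUE)
    waters <- if ((fx$n_waters %||% 0) > 0) {
      make_water_shell(s$fragment, fx$n_waters, fx$r_min %||% 2.5,
                       fx$r_max %||% 6, seed = cfg$seed)
    }
    path <- file.path(cfg$output_dir, "fixture.pdb")
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mini_pdb(list(s$fragment), waters = waters, path = path)
    return(read_pdb(path))
  }
  stop("unknown fixture kind: ", fx$kind)
}

#' Pipeline stage: prepare the chromophore QM region
#'
#' Extracts the chromophore named in the configuration, places hydrogens,
#' imposes the protonated form, and writes the fragment as XYZ and PDB
#' together with a checksum manifest.
#'
#' @param config configuration (path or list, see [load_run_config()]).
#' @return list with the fragment and output paths, invisibly.
#' @export
run_prepare <- function(config) {
  cfg <- load_run_config(config)
  stage_try("prepare", {
    struct <- load_structure(cfg)
    spec <- config_chromophore_spec(cfg)
    frag <- extract_chromophore(struct, spec)
    frag <- place_hydrogens(frag)
    frag <- protonate_chromophore(frag, spec)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    xyz <- file.path(cfg$output_dir, "fragment.xyz")
    pdbf <- file.path(cfg$output_dir, "fragment.pdb")
    write_xyz(frag, xyz)
    write_mini_pdb(list(frag), path = pdbf)
    write_manifest(cfg, "prepare",
                   inputs = list(structure = cfg$structure$pdb %||%
                                   file.path(cfg$output_dir,
                                             "fixture.pdb")),
                   outputs = list(fragment_xyz = xyz,
                                  fragment_pdb = pdbf))
    invisible(list(fragment = frag, xyz = xyz, pdb = pdbf))
  })
}

#' Pipeline stage: residue and water point charges
#'
#' Runs the sliding capped-tripeptide protocol over the configured chains
#' and assigns fixed charges to any waters in the structure; the combined
#' candidate charge set is written as a TSV for the later stages.
#'
#' @param config configuration (path or list).
#' @return list with the charge table and output path, invisibly.
#' @export
run_charges <- function(config) {
  cfg <- load_run_config(config)
  stage_try("charges", {
    struct <- load_structure(cfg)
    params <- config_params(cfg)
    engine <- cfg$charges$engine %||% "scf"
    chains <- cfg$charges$chains %||%
      unique(struct$atoms$chain[struct$atoms$kind == "polymer"])
    tabs <- list()
    for (ch in chains) {
      windows <- build_tripeptide_windows(struct, ch)
      message("charges: chain ", ch, ": ", length(windows), " windows")
      tabs[[ch]] <- derive_residue_charges(windows, params,
                                           engine = engine)
    }
    tab <- do.call(rbind, tabs)
    sources <- if (!is.null(tab)) {
      data.frame(x = tab$x, y = tab$y, z = tab$z, q = tab$q,
                 source = "protein",
                 origin = paste0(tab$chain, tab$resno, ":",
                                 tab$atom_name),
                 chain = tab$chain, resno = tab$resno,
                 atom_name = tab$atom_name, stringsAsFactors = FALSE)
    }
    wat <- struct$atoms[struct$atoms$kind == "water", , drop = FALSE]
    if (nrow(wat)) {
      wat$water <- match(paste(wat$chain, wat$resno),
                         unique(paste(wat$chain, wat$resno)))
      wq <- assign_water_charges(wat[order(wat$water,
                                           wat$element != "O"),
                                     c("water", "element", "x", "y",
                                       "z")])
      wq$chain <- "W"; wq$resno <- NA; wq$atom_name <- NA
      sources <- if (is.null(sources)) wq else
        rbind(sources, wq[, names(sources)])
    }
    if (is.null(sources)) stop("structure provides no polymer chains or",
                               " waters to build charges from")
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(cfg$output_dir, "charge_sources.tsv")
    write_charge_table(sources, tsv)
    if (!is.null(tab)) {
      write_charge_table(tab, file.path(cfg$output_dir,
                                        "charge_table.tsv"))
    }
    write_manifest(cfg, "charges", inputs = list(),
                   outputs = list(charge_sources = tsv))
    invisible(list(sources = sources, path = tsv))
  })
}

#' @keywords internal
load_prepared_fragment <- function(cfg) {
  xyz <- file.path(cfg$output_dir, "fragment.xyz")
  if (!file.exists(xyz)) stop("no prepared fragment at ", xyz,
                              "; run run_prepare() first")
  read_xyz(xyz)
}

#' @keywords internal
load_charge_sources <- function(cfg) {
  if (!is.null(cfg$spectrum$environment)) {
    return(read_environment(cfg$spectrum$environment))
  }
  tsv <- file.path(cfg$output_dir, "charge_sources.tsv")
  if (file.exists(tsv)) return(read_charge_table(tsv))
  NULL
}

#' Pipeline stage: absorption spectrum for one environment
#'
#' Embeds the prepared fragment in the point charges within the
#' configured radius, runs SCF + CI, and writes the stick spectrum.
#'
#' @param config configuration (path or list).
#' @return the `indo_spectrum`, invisibly.
#' @export
run_spectrum <- function(config) {
  cfg <- load_run_config(config)
  stage_try("spectrum", {
    params <- config_params(cfg)
    frag <- load_prepared_fragment(cfg)
    sources <- load_charge_sources(cfg)
    R <- cfg$spectrum$radius %||% 8
    env <- if (!is.null(sources) && nrow(sources)) {
      e <- build_environment(sources, frag, R,
                             spec = config_chromophore_spec(cfg),
                             label = "configured")
      neutralize_with_counter_ions(e, cfg$charges$counter_ion_seed %||%
                                     cfg$seed)
    }
    sp <- compute_spectrum(frag, params, environment = env,
                           n_singles = cfg$ci$n_singles,
                           include_paired_doubles =
                             cfg$ci$include_paired_doubles,
                           label = if (is.null(env)) "vacuum"
                                   else sprintf("R=%g", R))
    tsv <- file.path(cfg$output_dir, "spectrum.tsv")
    export_spectrum(sp, tsv)
    message(sprintf("spectrum: lambda1 = %.1f nm, f1 = %.3f",
                    sp$states$wavelength_nm[1],
                    sp$states$oscillator_strength[1]))
    write_manifest(cfg, "spectrum", inputs = list(),
                   outputs = list(spectrum = tsv))
    invisible(sp)
  })
}

#' Pipeline stage: radius scan
#'
#' @param config configuration (path or list).
#' @return the `radius_scan`, invisibly.
#' @export
run_scan <- function(config) {
  cfg <- load_run_config(config)
  stage_try("scan", {
    params <- config_params(cfg)
    frag <- load_prepared_fragment(cfg)
    sources <- load_charge_sources(cfg)
    if (is.null(sources)) stop("no charge sources; run run_charges()")
    label <- cfg$scan$label %||% "scan"
    sc <- radius_scan(frag, sources, cfg$scan$radii %||% 0:8, params,
                      exclusions = cfg$scan$exclusions,
                      spec = config_chromophore_spec(cfg),
                      n_singles = cfg$ci$n_singles,
                      include_paired_doubles =
                        cfg$ci$include_paired_doubles,
                      label = label)
    tsv <- file.path(cfg$output_dir, paste0("scan_", label, ".tsv"))
    utils::write.table(sc$rows, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_manifest(cfg, "scan", inputs = list(),
                   outputs = stats::setNames(list(tsv), label))
    invisible(sc)
  })
}

#' Pipeline stage: compare environment models
#'
#' Each configured model selects the charge sources with its own
#' exclusions at the configured radius; the comparison table of
#' lambda_1 / f_1 / delta lambda is written as TSV.
#'
#' @param config configuration (path or list).
#' @return the comparison data frame, invisibly.
#' @export
run_compare <- function(config) {
  cfg <- load_run_config(config)
  stage_try("compare", {
    params <- config_params(cfg)
    frag <- load_prepared_fragment(cfg)
    sources <- load_charge_sources(cfg)
    if (is.null(sources)) stop("no charge sources; run run_charges()")
    R <- cfg$spectrum$radius %||% 8
    spec <- config_chromophore_spec(cfg)
    envs <- lapply(cfg$compare$models, function(m) {
      build_environment(sources, frag, R, exclusions = m$exclusions,
                        spec = spec, label = m$label)
    })
    cmp <- compare_models(frag, envs, params,
                          n_singles = cfg$ci$n_singles,
                          include_paired_doubles =
                            cfg$ci$include_paired_doubles)
    tsv <- file.path(cfg$output_dir, "compare.tsv")
    utils::write.table(cmp, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_manifest(cfg, "compare", inputs = list(),
                   outputs = list(compare = tsv))
    invisible(cmp)
  })
}

#' Pipeline stage: write the synthetic fixture set
#'
#' Writes the toy molecules, the surrogate, a seeded water shell and a
#' charge shell into the output directory.
#'
#' @param config configuration (path or list).
#' @return vector of written paths, invisibly.
#' @export
run_fixtures <- function(config) {
  cfg <- load_run_config(config)
  stage_try("fixtures", {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (nm in c("ethylene", "s_trans_butadiene", "hexatriene",
                 "formaldehyde", "water", "pyrrole")) {
      f <- file.path(cfg$output_dir, paste0(nm, ".xyz"))
      write_xyz(make_toy_molecule(nm), f)
      paths <- c(paths, f)
    }
    s <- make_pcb_surrogate()
    w <- make_water_shell(s$fragment, 10, seed = cfg$seed)
    f <- file.path(cfg$output_dir, "surrogate.pdb")
    write_mini_pdb(list(s$fragment), waters = w, path = f)
    paths <- c(paths, f)
    sh <- make_charge_shell(c(0, 0, 0), 10, 50, -1)
    f <- file.path(cfg$output_dir, "charge_shell.tsv")
    utils::write.table(sh, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
    write_manifest(cfg, "fixtures", inputs = list(),
                   outputs = as.list(stats::setNames(paths,
                                                     basename(paths))))
    invisible(paths)
  })
}
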