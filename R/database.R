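#' Molecular formula of a lipid species
#'
#' Assembles the elemental formula from the class backbone plus the
#' combined acyl contribution. For a composition with C total carbons,
#' DB double bonds and c cyclopropane rings spread over n chains, the
#' acyl chains contribute \eqn{C_C H_{2C - 2(DB + c)} O_{2n}} as free
#' fatty acids, and one water is condensed out per ester/amide linkage.
#' A cyclopropane ring costs two hydrogens, exactly like one double bond,
#' so e.g. PE 33:0c1 and PE 33:1 share one formula (and one m/z).
#'
#' @param class_name Lipid class (see [lipid_classes()]).
#' @param total_carbons,double_bonds,cyclopropane Acyl composition
#'   totals over all chains.
#' @return An [elemental_formula()].
#' @examples
#' formula_string(molecular_formula("PE", 34, 1)) # "C39H76NO8P"
#' @export
molecular_formula <- function(class_name, total_carbons, double_bonds,
                              cyclopropane = 0L) {
  def <- class_def(class_name)
  n <- def$n_chains
  validate_composition(class_name, total_carbons, double_bonds, cyclopropane)
  backbone <- parse_formula(def$backbone)
  m <- double_bonds + cyclopropane
  acyl <- elemental_formula(C = total_carbons, H = 2 * total_carbons - 2 * m,
                            O = 2 * n)
  water <- elemental_formula(H = 2 * n, O = n)
  formula_subtract(formula_add(backbone, acyl), water)
}

validate_composition <- function(class_name, total_carbons, double_bonds,
                                 cyclopropane, min_chain_carbons = 2L) {
  def <- class_def(class_name)
  if (total_carbons < min_chain_carbons * def$n_chains) {
    abort(paste0("Total carbons (", total_carbons, ") below the minimum for ",
                 class_name, " (", min_chain_carbons * def$n_chains, ")."))
  }
  if (double_bonds < 0 || cyclopropane < 0 || cyclopropane > 2) {
    abort("double_bonds must be >= 0 and cyclopropane in 0..2.")
  }
  invisible(TRUE)
}

#' Database enumeration configuration
#'
#' Per-class acyl ranges for [lipid_database()]. The defaults span the
#' species observed in an E. coli knock-out/overexpression screen
#' (diacyl classes around C28-C40, headgroup acylates C46-C52,
#' cardiolipin C64-C72) and enumerate 231 canonical species over the
#' eleven classes.
#'
#' @param classes Named list; each entry is
#'   `list(carbons = c(min, max), max_mod = <DB + ring cap>,
#'   cyclopropane = <max rings>)`. Defaults cover all eleven classes.
#' @param mz_range Instrument scan range used to filter the database
#'   (default 350-1750 Th).
#' @param p13c 13C natural abundance used for isotope envelopes.
#' @return List with class `db_config`.
#' @export
db_config <- function(classes = NULL, mz_range = c(350, 1750), p13c = 0.011) {
  default_classes <- list(
    PE        = list(carbons = c(28, 40), max_mod = 2, cyclopropane = 1),
    PG        = list(carbons = c(28, 40), max_mod = 2, cyclopropane = 1),
    PA        = list(carbons = c(30, 36), max_mod = 1, cyclopropane = 1),
    PS        = list(carbons = c(30, 36), max_mod = 1, cyclopropane = 1),
    PGP       = list(carbons = c(30, 36), max_mod = 1, cyclopropane = 1),
    `CDP-DAG` = list(carbons = c(30, 36), max_mod = 1, cyclopropane = 1),
    CL        = list(carbons = c(64, 72), max_mod = 2, cyclopropane = 1),
    DLCL      = list(carbons = c(28, 36), max_mod = 1, cyclopropane = 1),
    aPE       = list(carbons = c(46, 52), max_mod = 2, cyclopropane = 1),
    aPG       = list(carbons = c(46, 52), max_mod = 2, cyclopropane = 1),
    PBut      = list(carbons = c(32, 36), max_mod = 1, cyclopropane = 1)
  )
  structure(list(classes = classes %||% default_classes,
                 mz_range = mz_range, p13c = p13c),
            class = "db_config")
}

#' Build the in-silico lipid database
#'
#' Enumerates every (class, total carbons, double bonds, cyclopropane)
#' combination allowed by the configuration, assembles elemental formulas
#' and deprotonated monoisotopic masses, and filters to the instrument
#' scan range. Cyclopropane rings are isobaric with double bonds, so the
#' database deliberately carries both annotations of each isobar as
#' distinct rows sharing one m/z; the `canonical` flag marks the name the
#' annotator reports, following the odd/even carbon convention (E. coli
#' synthesizes cyclopropane rings on odd-total species, since Cfa adds a
#' methylene across a double bond).
#'
#' @param config A [db_config()].
#' @return Tibble with one row per species: `class`, `name`,
#'   `total_carbons`, `double_bonds`, `cyclopropane`, `n_chains`,
#'   `formula`, `mz`, `rt_min`, `rt_max`, `rt_center`, `canonical`;
#'   sorted by class then m/z then name.
#' @examples
#' db <- lipid_database(db_config())
#' nrow(dplyr::filter(db, canonical)) # 231 species
#' @export
lipid_database <- function(config = db_config()) {
  stopifnot(inherits(config, "db_config"))
  if (length(config$classes) == 0) {
    warn("Empty database configuration: returning an empty database.")
    return(empty_database())
  }
  cls_info <- lipid_classes()
  rows <- purrr::imap(config$classes, function(cfg, cls) {
    cap <- cfg$max_mod
    grid <- expand.grid(total_carbons = seq(cfg$carbons[1], cfg$carbons[2]),
                        double_bonds = 0:cap,
                        cyclopropane = 0:cfg$cyclopropane)
    grid <- grid[grid$double_bonds + grid$cyclopropane <= cap, , drop = FALSE]
    grid$class <- cls
    grid
  })
  db <- dplyr::bind_rows(rows)
  db <- dplyr::distinct(db, .data$class, .data$total_carbons,
                        .data$double_bonds, .data$cyclopropane)
  db$name <- build_species_name(db$class, db$total_carbons,
                                db$double_bonds, db$cyclopropane)
  forms <- purrr::pmap(
    list(db$class, db$total_carbons, db$double_bonds, db$cyclopropane),
    molecular_formula)
  db$formula <- vapply(forms, formula_string, character(1))
  db$mz <- vapply(forms, monoisotopic_mz, numeric(1))
  db <- db[db$mz >= config$mz_range[1] & db$mz <= config$mz_range[2], ,
           drop = FALSE]
  db <- dplyr::left_join(db, cls_info, by = "class")
  # canonical naming of isobars: odd total carbons -> cyclopropane (c1)
  # annotation, even -> plain double-bond annotation
  db$canonical <- ifelse(db$total_carbons %% 2L == 1L,
                         db$cyclopropane == pmin(1L, db$double_bonds +
                                                   db$cyclopropane),
                         db$cyclopropane == 0L)
  db <- db[order(match(db$class, cls_info$class), db$mz, db$name), ]
  as_tibble(db[, c("class", "name", "total_carbons", "double_bonds",
                   "cyclopropane", "n_chains", "formula", "mz",
                   "rt_min", "rt_max", "rt_center", "canonical")])
}

empty_database <- function() {
  tibble(class = character(), name = character(),
         total_carbons = integer(), double_bonds = integer(),
         cyclopropane = integer(), n_chains = integer(),
         formula = character(), mz = numeric(),
         rt_min = numeric(), rt_max = numeric(), rt_center = numeric(),
         canonical = logical())
}

#' Export / import a lipid database
#'
#' CSV or JSON round-trip of the database table.
#'
#' @param db Database tibble from [lipid_database()].
#' @param path Output file; format chosen from the extension
#'   (`.csv` or `.json`).
#' @return `write_lipid_database()` returns `path` invisibly;
#'   `read_lipid_database()` returns the database tibble.
#' @export
write_lipid_database <- function(db, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(db, path, digits = NA)
  } else {
    readr::write_csv(db, path)
  }
  invisible(path)
}

#' @rdname write_lipid_database
#' @export
read_lipid_database <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
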