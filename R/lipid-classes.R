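# Class-level constants for the E. coli glycerophospholipidome.
#
# backbone = elemental composition of the fully hydroxylated zero-acyl core
# (glycerophospho-headgroup with free hydroxyls/amine), so that
#   species formula = backbone + free fatty acids - one H2O per linkage.
# Backbones are data, not computed from structure drawings; tests verify
# two species per class against an independent structure-assembly oracle.
#
# rt windows (min) are conventions for a ~5-minute HILIC gradient in which
# retention is governed by the headgroup; adjacent windows deliberately
# overlap slightly and ambiguous features are resolved by nearest window
# center.
.LIPID_CLASS_TABLE <- data.frame(
  class     = c("PBut", "PA", "PG", "aPG", "CL", "DLCL",
                "PE", "aPE", "PS", "PGP", "CDP-DAG"),
  n_chains  = c(2L, 2L, 2L, 3L, 4L, 2L,
                2L, 3L, 2L, 2L, 2L),
  backbone  = c("C7H17O6P", "C3H9O6P", "C6H15O8P", "C6H15O8P",
                "C9H22O13P2", "C9H22O13P2",
                "C5H14NO6P", "C5H14NO6P", "C6H14NO8P",
                "C6H16O11P2", "C12H21N3O13P2"),
  rt_min    = c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8, 2.1, 2.4, 2.7, 3.0, 3.3),
  rt_max    = c(0.7, 1.0, 1.3, 1.6, 1.9, 2.2, 2.5, 2.8, 3.1, 3.4, 3.7),
  stringsAsFactors = FALSE
)

#' Glycerophospholipid class definitions
#'
#' Definitions of the eleven phospholipid classes covered by the in-silico
#' database: phosphatidic acid (PA), phosphatidylethanolamine (PE),
#' phosphatidylglycerol (PG), phosphatidylserine (PS),
#' phosphatidylglycerolphosphate (PGP), CDP-diacylglycerol (CDP-DAG),
#' cardiolipin (CL), di-lyso cardiolipin (DLCL), the headgroup-acylated
#' classes N-acyl-PE (aPE) and O-acyl-PG (aPG), and phosphatidylbutanol
#' (PBut), the transphosphatidylation product formed from n-butanol.
#'
#' Each class carries the number of acyl chains (2 for diacyl classes,
#' 3 for headgroup acylates, 4 for CL), the elemental backbone of the
#' zero-acyl core, and the HILIC retention-time window (minutes) used to
#' assign features to classes.
#'
#' @return Tibble with columns `class`, `n_chains`, `backbone`, `rt_min`,
#'   `rt_max`, `rt_center`.
#' @export
lipid_classes <- function() {
  out <- as_tibble(.LIPID_CLASS_TABLE)
  out$rt_center <- (out$rt_min + out$rt_max) / 2
  out
}

class_def <- function(class_name) {
  i <- match(class_name, .LIPID_CLASS_TABLE$class)
  if (is.na(i)) {
    abort(paste0("Unknown lipid class: '", class_name, "'"))
  }
  .LIPID_CLASS_TABLE[i, , drop = FALSE]
}

#' Canonical species name from class and acyl composition
#'
#' Species-level nomenclature: `"<CLASS> <C>:<DB>"` where C is the total
#' acyl carbon count and DB the total number of double bonds, with suffix
#' `c<k>` when the chains carry k >= 1 cyclopropane rings (e.g.
#' `"PE 33:0c1"`, the Cfa product of PE 32:1).
#'
#' @param class_name Lipid class (see [lipid_classes()]).
#' @param total_carbons,double_bonds,cyclopropane Acyl composition.
#' @return Character vector of species names.
#' @examples
#' build_species_name("PE", 34, 1)      # "PE 34:1"
#' build_species_name("PE", 33, 0, 1)   # "PE 33:0c1"
#' @export
build_species_name <- function(class_name, total_carbons, double_bonds,
                               cyclopropane = 0L) {
  bad <- setdiff(unique(class_name), .LIPID_CLASS_TABLE$class)
  if (length(bad) > 0) {
    abort(paste0("Unknown lipid class: '", bad[[1]], "'"))
  }
  suffix <- ifelse(cyclopropane >= 1, paste0("c", cyclopropane), "")
  paste0(class_name, " ", total_carbons, ":", double_bonds, suffix)
}

#' Parse a species name into class and acyl composition
#'
#' Inverse of [build_species_name()]: `parse(build(x)) == x` for every
#' valid composition.
#'
#' @param name Character vector of species names such as `"PG 35:0c1"`.
#' @return Tibble with columns `name`, `class`, `total_carbons`,
#'   `double_bonds`, `cyclopropane`.
#' @examples
#' parse_species_name(c("PE 32:1", "PG 35:0c1"))
#' @export
parse_species_name <- function(name) {
  m <- regexec("^([A-Za-z-]+) ([0-9]+):([0-9]+)(?:c([0-9]+))?$", name)
  parts <- regmatches(name, m)
  bad <- name[lengths(parts) == 0]
  if (length(bad) > 0) {
    abort(paste0("Malformed species name: '", bad[[1]], "'"))
  }
  cls <- vapply(parts, `[[`, character(1), 2)
  unknown <- setdiff(unique(cls), .LIPID_CLASS_TABLE$class)
  if (length(unknown) > 0) {
    abort(paste0("Unknown lipid class: '", unknown[[1]], "'"))
  }
  tibble(
    name = name,
    class = cls,
    total_carbons = as.integer(vapply(parts, `[[`, character(1), 3)),
    double_bonds = as.integer(vapply(parts, `[[`, character(1), 4)),
    cyclopropane = as.integer(
      ifelse(vapply(parts, `[[`, character(1), 5) == "", "0",
             vapply(parts, `[[`, character(1), 5)))
  )
}
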