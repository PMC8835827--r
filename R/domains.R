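#' Construct a domain map
#'
#' Named residue ranges for a multidomain architecture, plus "hint" segments:
#' short, structurally stable secondary-structure elements whose axes serve
#' as reference vectors for relative-orientation measurements.  Standard
#' names for the KIT cytoplasmic region: TM, JMR (sub-segments JM-P, JM-B,
#' JM-S, JM-Z), NLOBE, HINGE, CLOBE, KID, ALOOP, CTAIL.
#'
#' @param domains named list; each entry a list of \code{c(first, last)}
#'   residue ranges (or one such vector).
#' @param hints named list of \code{c(first, last)} hint segments.
#' @return object of class \code{"domain_map"}.
#' @export
domain_map <- function(domains, hints = list()) {
  norm <- function(x) if (is.list(x)) lapply(x, as.integer) else list(as.integer(x))
  domains <- lapply(domains, norm)
  for (nm in names(domains))
    for (r in domains[[nm]]) {
      if (length(r) != 2L || r[2] < r[1])
        stop("domain ", nm, ": ranges must be c(first, last) with last >= first")
    }
  hints <- lapply(hints, as.integer)
  # JMR sub-segments must not overlap each other
  subs <- intersect(names(domains), c("JM-P", "JM-B", "JM-S", "JM-Z"))
  if (length(subs) > 1) {
    res <- lapply(subs, function(nm) range_residues(domains[[nm]]))
    all_res <- unlist(res)
    if (anyDuplicated(all_res))
      stop("JMR sub-segments overlap: residue(s) ",
           paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  }
  structure(list(domains = domains, hints = hints), class = "domain_map")
}

#' Residues of one named domain
#' @param map a \code{\link{domain_map}}.
#' @param name domain name.
#' @export
domain_residues <- function(map, name) {
  if (!name %in% names(map$domains)) stop("unknown domain: ", name)
  range_residues(map$domains[[name]])
}

#' @export
print.domain_map <- function(x, ...) {
  for (nm in names(x$domains)) {
    rr <- vapply(x$domains[[nm]], function(r) paste(r, collapse = "-"), "")
    cat(sprintf("%-8s %s\n", nm, paste(rr, collapse = ", ")))
  }
  if (length(x$hints))
    cat("hints:", paste(names(x$hints), collapse = ", "), "\n")
  invisible(x)
}

#' Load and validate a domain map from a YAML config
#'
#' Config layout: top-level \code{domains:} mapping name to a range
#' ("first-last") or list of ranges, and optional \code{hints:} mapping
#' segment name to "first-last".  Every declared residue must exist in the
#' topology; unresolved residues raise a validation error listing them.
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @param top a \code{\link{topology}} to validate against, or NULL to skip
#'   validation.
#' @return a validated \code{\link{domain_map}}.
#' @export
load_domain_map <- function(config, top = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$domains) || length(config$domains) == 0)
    stop("config must declare at least one named range under 'domains'")
  parse_range <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    v <- as.integer(strsplit(as.character(x), "[-:]")[[1]])
    if (length(v) != 2L || anyNA(v)) stop("cannot parse range: ", x)
    v
  }
  doms <- lapply(config$domains, function(d) {
    if (is.list(d)) lapply(d, parse_range) else list(parse_range(d))
  })
  hints <- lapply(config$hints %||% list(), parse_range)
  map <- domain_map(doms, hints)
  if (!is.null(top)) validate_domain_map(map, top)
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a domain map against a topology
#'
#' @param map a \code{\link{domain_map}}.
#' @param top a \code{\link{topology}}.
#' @return invisibly TRUE; raises an error naming every unresolved residue.
#' @export
validate_domain_map <- function(map, top) {
  present <- unique(top$res_index)
  offenders <- character(0)
  check <- function(nm, residues) {
    missing <- setdiff(residues, present)
    if (length(missing))
      offenders <<- c(offenders, sprintf("%s: %s", nm,
                                         paste(missing, collapse = ",")))
  }
  for (nm in names(map$domains)) check(nm, range_residues(map$domains[[nm]]))
  for (nm in names(map$hints)) check(paste0("hint ", nm),
                                     range_residues(list(map$hints[[nm]])))
  if (length(offenders))
    stop("domain map references absent residues -- ",
         paste(offenders, collapse = "; "))
  invisible(TRUE)
}

#' Serialize a domain map back to the canonical config form
#'
#' @param map a \code{\link{domain_map}}.
#' @return list in the layout accepted by \code{\link{load_domain_map}};
#'   \code{load_domain_map(serialize_domain_map(m))} reproduces \code{m}.
#' @export
serialize_domain_map <- function(map) {
  fmt <- function(r) paste0(r[1], "-", r[2])
  list(domains = lapply(map$domains, function(d)
         if (length(d) == 1) fmt(d[[1]]) else lapply(d, fmt)),
       hints = lapply(map$hints, fmt))
}

#' Canonical domain map of the KIT cytoplasmic region
#'
#' Residue numbering follows the UniProt/author convention for the
#' cytoplasmic construct I516--R946.  Boundaries: TM helix L525--Y545,
#' juxtamembrane region K546--K581 with sub-segments JM-P T544--D552,
#' JM-B Y553--V559, JM-S V560--I571, JM-Z D572--K581, tyrosine-kinase
#' domain W582--S931 split into N-lobe, hinge and C-lobe around the kinase
#' insert domain (KID, S689--L768, taken as the complement of the rigid-core
#' fit selection within the TK domain), activation loop D810--E839
#' (extended A-loop), and C-terminal tail T932--R946.  Hint segments are the
#' most structurally stable elements: P524--C537 (TM helix; note this hint
#' starts one residue before the declared TM domain, and published boundary
#' conventions for the TM segment differ by a few residues), T594--A597
#' (beta1 of the P-loop), L637--G648 (alphaC helix), A701--N705 (alphaH1 of
#' KID), S771--L783 (alphaE of the C-lobe) and V824--K826 (beta9 of the
#' A-loop).
#'
#' @return a \code{\link{domain_map}}.
#' @export
kit_domain_map <- function() {
  load_domain_map(system.file("extdata", "kit_domains.yaml",
                              package = "kitdyn"))
}

#' Default rigid-core fit selection for the KIT tyrosine-kinase domain
#'
#' Residues W582--S688 plus L769--S931 (the TK domain minus KID), the
#' selection used to normalize all whole-protein analyses.
#'
#' @param atom_names atoms to fit on (default Calpha).
#' @export
tk_fit_selection <- function(atom_names = "CA") {
  selection(residues = c(582:688, 769:931), atom_names = atom_names)
}
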