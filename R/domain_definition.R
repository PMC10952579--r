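#' Residue reference table
#'
#' Helper building the (chain, resno, insert) tables used throughout a
#' \code{DomainDefinition}.
#'
#' @param chain chain id(s), recycled.
#' @param resno residue numbers (integer).
#' @param insert insertion codes, default "".
#' @return data frame with columns \code{chain}, \code{resno}, \code{insert}.
#' @export
resref <- function(chain, resno, insert = "") {
  if (length(resno) == 0L) {
    return(data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), stringsAsFactors = FALSE))
  }
  data.frame(chain = as.character(chain), resno = as.integer(resno),
             insert = as.character(insert), stringsAsFactors = FALSE)
}

#' Construct a DomainDefinition
#'
#' Named residue selections for a diabody (or single Fv): per site (A, B)
#' the V_H and V_L residue sets, beta-sheet masks, anchor tryptophans, hinge
#' residues, N-/C-terminal anchors, the V_H to V_L residue-equivalence table
#' used for the pseudo-dyad superposition, and CDR loop ranges. All residues
#' are explicit (chain, resno, insert) references in the numbering of the
#' bound structure; no Kabat renumbering is performed. Conserved positions
#' (e.g. the anchor tryptophans at Kabat W36/W35) are therefore supplied by
#' the user for real structures.
#'
#' @param sites named list (names "A" and optionally "B"); each site is a
#'   list with elements \code{vh}, \code{vl}, \code{sheet_vh}, \code{sheet_vl},
#'   \code{anchor_trp_vh}, \code{anchor_trp_vl} (single-row), \code{hinge},
#'   \code{nterm}, \code{cterm} (single-row each), optional \code{equivalence}
#'   (data frame chain_vh,resno_vh,insert_vh,chain_vl,resno_vl,insert_vl) and
#'   optional \code{cdr} (named list of resref tables, e.g. H1..H3, L1..L3).
#' @param dihedral_order character(4) of anchor tokens among
#'   \code{"vl_A","vh_A","vh_B","vl_B"}; the default spans the V_H-V_H
#'   interface with the central virtual bond.
#' @return object of class \code{DomainDefinition}.
#' @export
domain_definition <- function(sites,
                              dihedral_order = c("vl_A", "vh_A", "vh_B", "vl_B")) {
  stopifnot(is.list(sites), length(sites) >= 1, !is.null(names(sites)))
  for (s in names(sites)) {
    st <- sites[[s]]
    for (el in c("vh", "vl", "sheet_vh", "sheet_vl",
                 "anchor_trp_vh", "anchor_trp_vl", "hinge", "nterm", "cterm")) {
      if (is.null(st[[el]])) stop("domain_definition(): site ", s,
                                  " lacks element '", el, "'")
    }
    kh <- with(st$vh, paste(chain, resno, insert))
    kl <- with(st$vl, paste(chain, resno, insert))
    if (length(intersect(kh, kl))) {
      stop("domain_definition(): V_H and V_L selections overlap in site ", s)
    }
  }
  structure(list(sites = sites, dihedral_order = dihedral_order),
            class = "DomainDefinition")
}

#' @export
print.DomainDefinition <- function(x, ...) {
  cat("DomainDefinition:", length(x$sites), "site(s):",
      paste(names(x$sites), collapse = ", "), "\n")
  for (s in names(x$sites)) {
    st <- x$sites[[s]]
    cat("  site", s, ": V_H", nrow(st$vh), "res, V_L", nrow(st$vl),
        "res, sheet", nrow(st$sheet_vh) + nrow(st$sheet_vl), "res")
    if (!is.null(st$cdr)) cat(",", length(st$cdr), "CDR loops")
    cat("\n")
  }
  invisible(x)
}

# fetch a named selection from a DomainDefinition; names look like
# "vh_A", "sheet_vl_B", "hinge_A", "anchor_trp_vh_A", "cdr_H1_A"
#' @keywords internal
get_selection <- function(defn, name) {
  m <- regmatches(name, regexec("^(.*)_([AB])$", name))[[1]]
  if (length(m) != 3L) stop("get_selection(): bad selection name '", name, "'")
  base <- m[2]; site <- m[3]
  st <- defn$sites[[site]]
  if (is.null(st)) stop("get_selection(): no site '", site, "' declared")
  if (startsWith(base, "cdr_")) {
    loop <- sub("^cdr_", "", base)
    sel <- st$cdr[[loop]]
    if (is.null(sel)) stop("get_selection(): no CDR loop '", loop,
                           "' in site ", site)
    return(sel)
  }
  if (base == "hinge_sheet") {  # convenience: both sheets, V_H first
    return(rbind(st$sheet_vh, st$sheet_vl))
  }
  sel <- st[[base]]
  if (is.null(sel) || !is.data.frame(sel)) {
    stop("get_selection(): selection '", name, "' not declared")
  }
  sel
}

#' Resolve a named selection to atom indices
#'
#' Maps a selection declared in a \code{DomainDefinition} onto row indices of
#' a model's atom table. The output order follows the definition's residue
#' order (not file order); under \code{"CA-only"} exactly one index per
#' residue is returned, under \code{"backbone"} the N, CA, C, O atoms of each
#' residue in that order.
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition}.
#' @param name selection name, e.g. \code{"sheet_vh_A"}, \code{"vl_B"},
#'   \code{"cdr_H1_A"}.
#' @param atom_filter one of \code{"CA-only"}, \code{"backbone"}, \code{"all"}.
#' @return integer vector of atom row indices.
#' @export
resolve_selection <- function(model, defn, name,
                              atom_filter = c("CA-only", "backbone", "all")) {
  atom_filter <- match.arg(atom_filter)
  sel <- get_selection(defn, name)
  resolve_residues(model, sel, atom_filter, what = name)
}

# shared residue-table resolver
#' @keywords internal
resolve_residues <- function(model, sel, atom_filter, what = "selection") {
  at <- model$atoms
  key <- paste(at$chain, at$resno, at$insert)
  out <- integer(0)
  for (i in seq_len(nrow(sel))) {
    k <- paste(sel$chain[i], sel$resno[i], sel$insert[i])
    idx <- which(key == k)
    if (!length(idx)) {
      stop("resolve_selection(): residue (", sel$chain[i], " ", sel$resno[i],
           sel$insert[i], ") of '", what, "' missing from model")
    }
    if (atom_filter == "CA-only") {
      ca <- idx[at$elety[idx] == "CA"]
      if (length(ca) != 1L) {
        stop("resolve_selection(): residue (", sel$chain[i], " ",
             sel$resno[i], ") lacks a unique CA atom")
      }
      out <- c(out, ca)
    } else if (atom_filter == "backbone") {
      for (nm in c("N", "CA", "C", "O")) {
        a <- idx[at$elety[idx] == nm]
        if (length(a) != 1L) {
          stop("resolve_selection(): residue (", sel$chain[i], " ",
               sel$resno[i], ") lacks backbone atom ", nm)
        }
        out <- c(out, a)
      }
    } else {
      out <- c(out, idx)
    }
  }
  out
}

#' Validate a DomainDefinition against a structure
#'
#' Checks that every referenced residue exists in the model and that the
#' anchor residues are tryptophans. A non-TRP anchor is a warning only
#' (engineered variants may substitute it); missing residues are errors.
#'
#' @param model a \code{StructureModel}.
#' @param defn a \code{DomainDefinition}.
#' @return \code{TRUE} invisibly; errors/warnings otherwise.
#' @export
validate_definition <- function(model, defn) {
  at <- model$atoms
  key <- paste(at$chain, at$resno, at$insert)
  for (s in names(defn$sites)) {
    st <- defn$sites[[s]]
    tabs <- c(st[c("vh", "vl", "sheet_vh", "sheet_vl", "anchor_trp_vh",
                   "anchor_trp_vl", "hinge", "nterm", "cterm")],
              if (!is.null(st$cdr)) st$cdr)
    for (nm in names(tabs)) {
      sel <- tabs[[nm]]
      k <- paste(sel$chain, sel$resno, sel$insert)
      bad <- which(!(k %in% key))
      if (length(bad)) {
        stop("validate_definition(): residue (", sel$chain[bad[1]], " ",
             sel$resno[bad[1]], ") of ", nm, " (site ", s,
             ") missing from model")
      }
    }
    for (nm in c("anchor_trp_vh", "anchor_trp_vl")) {
      sel <- st[[nm]]
      k <- paste(sel$chain[1], sel$resno[1], sel$insert[1])
      rn <- unique(at$resid[key == k])
      if (!identical(rn, "TRP")) {
        warning("validate_definition(): anchor ", nm, " (site ", s,
                ") has residue name ", rn, ", not TRP")
      }
    }
  }
  invisible(TRUE)
}

# yaml helpers ---------------------------------------------------------------

#' @keywords internal
yaml_ranges_to_resref <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$chain)) x <- list(x)   # single entry
  do.call(rbind, lapply(x, function(r) {
    ins <- if (is.null(r$insert)) "" else r$insert
    if (!is.null(r$resno)) return(resref(r$chain, r$resno, ins))
    resref(r$chain, seq(r$from, r$to), ins)
  }))
}

#' Read a DomainDefinition from a YAML config file
#'
#' The config declares, per site, the residue selections used by every
#' descriptor. Schema (residue entries are either
#' \code{{chain, resno[, insert]}} or ranges \code{{chain, from, to}}, and
#' lists thereof):
#'
#' \preformatted{
#' dihedral_order: [vl_A, vh_A, vh_B, vl_B]   # optional
#' sites:
#'   A:
#'     vh:            [{chain: H, from: 1, to: 12}]
#'     vl:            [{chain: L, from: 1, to: 12}]
#'     sheet_vh:      [{chain: H, from: 2, to: 11}]
#'     sheet_vl:      [{chain: L, from: 2, to: 11}]
#'     anchor_trp_vh: {chain: H, resno: 6}
#'     anchor_trp_vl: {chain: L, resno: 6}
#'     hinge:         [{chain: H, resno: 12}, {chain: L, resno: 12}]
#'     nterm:         {chain: H, resno: 1}
#'     cterm:         {chain: H, resno: 12}
#'     equivalence:   # V_H residue i superposed onto V_L residue i
#'       vh: [{chain: H, from: 1, to: 12}]
#'       vl: [{chain: L, from: 1, to: 12}]
#'     cdr:
#'       H1: [{chain: H, from: 4, to: 8}]
#'   B: ...
#' }
#'
#' @param path YAML file path.
#' @return a \code{DomainDefinition}.
#' @export
read_domain_definition <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- lapply(y$sites, function(st) {
    out <- list()
    for (el in c("vh", "vl", "sheet_vh", "sheet_vl", "anchor_trp_vh",
                 "anchor_trp_vl", "hinge", "nterm", "cterm")) {
      out[[el]] <- yaml_ranges_to_resref(st[[el]])
    }
    if (!is.null(st$equivalence)) {
      eh <- yaml_ranges_to_resref(st$equivalence$vh)
      el2 <- yaml_ranges_to_resref(st$equivalence$vl)
      if (nrow(eh) != nrow(el2)) {
        stop("read_domain_definition(): equivalence tables differ in length")
      }
      out$equivalence <- data.frame(
        chain_vh = eh$chain, resno_vh = eh$resno, insert_vh = eh$insert,
        chain_vl = el2$chain, resno_vl = el2$resno, insert_vl = el2$insert,
        stringsAsFactors = FALSE)
    }
    if (!is.null(st$cdr)) out$cdr <- lapply(st$cdr, yaml_ranges_to_resref)
    out
  })
  dorder <- y$dihedral_order
  if (is.null(dorder)) dorder <- c("vl_A", "vh_A", "vh_B", "vl_B")
  domain_definition(sites, dihedral_order = unlist(dorder))
}
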