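#' Atom selections
#'
#' A selection is a conjunction of predicates over atoms: membership of the
#' atom name, residue name or species in given sets, leaflet side, and a
#' z-range. Name/residue/species predicates are frame-independent; the
#' leaflet and z-range predicates are evaluated per frame relative to the
#' bilayer centre (the mean z of all lipid-species atoms in that frame), so
#' "nitrogen atoms in the upper leaflet" is `selection(name = "NF",
#' leaflet = "upper")`.
#'
#' @param name,resname,species Character vectors of admissible values
#'   (`NULL` = no constraint).
#' @param leaflet `"upper"` or `"lower"` (`NULL` = both).
#' @param z_range Length-2 numeric range on z relative to the bilayer
#'   centre (`NULL` = no constraint).
#' @return An object of class `fr_selection`.
#' @export
selection <- function(name = NULL, resname = NULL, species = NULL,
                      leaflet = NULL, z_range = NULL) {
  if (!is.null(leaflet)) leaflet <- match.arg(leaflet, c("upper", "lower"))
  if (!is.null(z_range) && (length(z_range) != 2 || z_range[1] > z_range[2])) {
    abort("z_range must be an increasing length-2 range")
  }
  structure(
    list(name = name, resname = resname, species = species,
         leaflet = leaflet, z_range = z_range),
    class = "fr_selection"
  )
}

#' Parse a selection string
#'
#' Compact configuration syntax: space-separated `key:value[,value...]`
#' pairs with keys `name`, `resname`, `species`, `leaflet`, `zmin`, `zmax`,
#' e.g. `"name:NF leaflet:upper"`.
#'
#' @param x A selection string.
#' @return An [selection()].
#' @export
parse_selection <- function(x) {
  if (!nzchar(trimws(x))) {
    return(selection())
  }
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  kv <- strsplit(toks, ":", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) abort(sprintf("cannot parse selection token '%s'",
                                 toks[bad[1]]))
  args <- list()
  zmin <- -Inf
  zmax <- Inf
  for (p in kv) {
    key <- p[1]
    val <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    switch(key,
      name = args$name <- val,
      resname = args$resname <- val,
      species = args$species <- val,
      leaflet = args$leaflet <- val,
      zmin = zmin <- as.numeric(val),
      zmax = zmax <- as.numeric(val),
      abort(sprintf("unknown selection key '%s'", key))
    )
  }
  if (is.finite(zmin) || is.finite(zmax)) args$z_range <- c(zmin, zmax)
  do.call(selection, args)
}

#' Evaluate a selection on a frame
#'
#' @param top A [topology()].
#' @param sel An [selection()] (or a selection string).
#' @param xyz Frame coordinates (`n x 3`), needed only when the selection
#'   uses `leaflet` or `z_range`.
#' @return A sorted integer vector of atom ids (set semantics). Selections
#'   naming unknown atom/residue/species values match nothing for that
#'   predicate and raise a warning.
#' @export
select_atoms <- function(top, sel, xyz = NULL) {
  if (is.character(sel)) sel <- parse_selection(sel)
  keep <- rep(TRUE, n_atoms(top))
  check_known <- function(values, universe, what) {
    unknown <- setdiff(values, universe)
    if (length(unknown)) {
      warn(paste0("selection references unknown ", what, ": ",
                  paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(sel$name)) {
    check_known(sel$name, unique(top$name), "atom names")
    keep <- keep & top$name %in% sel$name
  }
  if (!is.null(sel$resname)) {
    check_known(sel$resname, unique(top$resname), "residue names")
    keep <- keep & top$resname %in% sel$resname
  }
  if (!is.null(sel$species)) {
    check_known(sel$species, unique(top$species), "species")
    keep <- keep & top$species %in% sel$species
  }
  if (!is.null(sel$leaflet) || !is.null(sel$z_range)) {
    if (is.null(xyz)) {
      abort("leaflet/z_range selections need frame coordinates")
    }
    zc <- xyz[, 3] - bilayer_center(top, xyz)
    if (!is.null(sel$leaflet)) {
      keep <- keep & if (sel$leaflet == "upper") zc >= 0 else zc < 0
    }
    if (!is.null(sel$z_range)) {
      keep <- keep & zc >= sel$z_range[1] & zc <= sel$z_range[2]
    }
  }
  sort(which(keep))
}
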