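# Atom mapping input/output. A reaction atom map is a bijection from substrate
# atoms to product atoms of the same element; atoms are keyed by
# (metabolite, instance, element, per-element 1-based index in molfile order),
# matching the convention that atoms of different elements are numbered
# separately.

.MAP_COLS <- c("reaction_id", "sub_met", "sub_instance", "element",
               "sub_index", "prod_met", "prod_instance", "prod_index")

.check_bijection <- function(tab, reaction_id) {
  if (any(tab$sub_index < 1) || any(tab$prod_index < 1)) {
    stop("atom indices must be >= 1 in reaction ", reaction_id)
  }
  skey <- paste(tab$sub_met, tab$sub_instance, tab$element, tab$sub_index)
  pkey <- paste(tab$prod_met, tab$prod_instance, tab$element, tab$prod_index)
  if (anyDuplicated(skey)) {
    stop("bijection violated in reaction ", reaction_id,
         ": substrate atom mapped twice")
  }
  if (anyDuplicated(pkey)) {
    stop("bijection violated in reaction ", reaction_id,
         ": product atom mapped twice")
  }
  invisible(TRUE)
}

#' Assemble an atom mapping set from per-reaction transition tables
#'
#' @param maps named list, one data frame per reaction with columns
#'   `sub_met`, `sub_instance`, `element`, `sub_index`, `prod_met`,
#'   `prod_instance`, `prod_index`. Names are reaction ids.
#' @return an object of class `atom_mapping_set`.
#' @export
atom_mapping_set <- function(maps) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  for (rid in names(maps)) {
    tab <- as.data.frame(maps[[rid]])
    need <- setdiff(.MAP_COLS[-1], names(tab))
    if (length(need)) stop("reaction ", rid, " map missing columns: ",
                           paste(need, collapse = ", "))
    .check_bijection(tab, rid)
    maps[[rid]] <- tab[, .MAP_COLS[-1]]
  }
  structure(maps, class = "atom_mapping_set")
}

#' @exportS3Method base::print
print.atom_mapping_set <- function(x, ...) {
  cat("<atom_mapping_set> ", length(x), " reaction(s), ",
      sum(vapply(x, nrow, integer(1))), " atom transitions\n", sep = "")
  invisible(x)
}

#' Parse a native tabular transition file into an atom mapping set
#'
#' The table has exactly the columns `reaction_id, sub_met, sub_instance,
#' element, sub_index, prod_met, prod_instance, prod_index`. Rows are grouped
#' per reaction and the bijection invariant is checked per reaction.
#'
#' @param path path to a TSV file, or a data frame with those columns.
#' @param net optional `metabolic_network` for cross-validation of reaction
#'   and metabolite ids.
#' @return an `atom_mapping_set`.
#' @export
parse_mapping_table <- function(path, net = NULL) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(
                        reaction_id = "character", sub_met = "character",
                        sub_instance = "integer", element = "character",
                        sub_index = "integer", prod_met = "character",
                        prod_instance = "integer", prod_index = "integer"
                      ))
  }
  if (!identical(names(tab), .MAP_COLS)) {
    stop("mapping table must have exactly the columns: ",
         paste(.MAP_COLS, collapse = ", "))
  }
  if (!is.null(net)) {
    bad_r <- setdiff(unique(tab$reaction_id), net$reactions$id)
    bad_m <- setdiff(unique(c(tab$sub_met, tab$prod_met)),
                     net$metabolites$id)
    if (length(bad_r)) stop("unknown reaction id(s): ",
                            paste(bad_r, collapse = ", "))
    if (length(bad_m)) stop("unknown metabolite id(s): ",
                            paste(bad_m, collapse = ", "))
  }
  if (nrow(tab) == 0) return(atom_mapping_set(stats::setNames(list(), character(0))))
  maps <- split(tab[, .MAP_COLS[-1]], tab$reaction_id)
  maps <- lapply(maps, function(d) { rownames(d) <- NULL; d })
  atom_mapping_set(maps)
}

#' Write an atom mapping set as a native TSV transition table
#'
#' Rows are sorted by (reaction_id, element, sub_met, sub_index) so output is
#' deterministic; `parse_mapping_table(write_mapping_table(x))` returns an
#' identical set.
#'
#' @param set an `atom_mapping_set`.
#' @param path output path; if `NULL` the table is returned invisibly only.
#' @return the table as a data frame, invisibly.
#' @export
write_mapping_table <- function(set, path = NULL) {
  stopifnot(inherits(set, "atom_mapping_set"))
  rows <- lapply(names(set), function(rid) {
    cbind(reaction_id = rid, set[[rid]])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    stats::setNames(
      data.frame(character(0), character(0), integer(0), character(0),
                 integer(0), character(0), integer(0), integer(0)),
      .MAP_COLS)
  }
  tab <- tab[order(tab$reaction_id, tab$element, tab$sub_met, tab$sub_index), ]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

# --- MDL RXN/MOL V2000 ------------------------------------------------------

# parse one V2000 molfile atom block; returns element symbols and atom-atom
# mapping numbers (columns 61-63; blank or 0 = unmapped) in molfile order
.parse_molfile_atoms <- function(lines) {
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(n_atoms)) stop("malformed molfile counts line: '", counts, "'")
  atom_lines <- lines[5:(4 + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  aam <- suppressWarnings(as.integer(substr(atom_lines, 61, 63)))
  aam[is.na(aam)] <- 0L
  data.frame(element = element, aam = aam, stringsAsFactors = FALSE)
}

#' Parse an MDL RXN V2000 record into a reaction atom map
#'
#' The record must start with `$RXN`; the counts line gives the number of
#' substrate and product molfiles; each V2000 atom block line carries the
#' atom-atom mapping number in columns 61-63 (blank or 0 = unmapped). A
#' substrate atom with mapping number `k` pairs with the product atom carrying
#' the same nonzero `k`. Per-element 1-based indices are assigned in molfile
#' atom-block order. Hydrogens are not inferred; molfiles used for
#' full-element analysis must list them explicitly.
#'
#' @param text the RXN record as a single string or character vector of lines.
#' @param reaction_id reaction identifier for the resulting map.
#' @param role_assignment data frame with columns `slot` (1-based molfile slot
#'   in record order, substrates first), `metabolite_id`, `instance`. Repeated
#'   molfiles for coefficients > 1 get instance numbers in slot order.
#' @param permissive if `TRUE`, unmapped atoms produce a warning instead of an
#'   error (diagnostic mode); the returned map covers mapped atoms only.
#' @return a one-reaction `atom_mapping_set` entry: a data frame of
#'   transitions with the unmapped atoms recorded in attribute `unmapped`.
#' @export
parse_rxn_v2000 <- function(text, reaction_id, role_assignment,
                            permissive = FALSE) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (!startsWith(trimws(lines[1]), "$RXN")) stop("record must start with $RXN")
  counts <- lines[5]
  ns <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  np <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(ns) || is.na(np)) stop("malformed RXN counts line: '", counts, "'")
  mol_starts <- which(startsWith(lines, "$MOL"))
  if (length(mol_starts) != ns + np) {
    stop("expected ", ns + np, " molfiles, found ", length(mol_starts))
  }
  role_assignment <- as.data.frame(role_assignment)
  stopifnot(all(c("slot", "metabolite_id", "instance") %in%
                names(role_assignment)))

  slot_atoms <- lapply(seq_along(mol_starts), function(k) {
    from <- mol_starts[k] + 1
    to <- if (k < length(mol_starts)) mol_starts[k + 1] - 1 else length(lines)
    atoms <- .parse_molfile_atoms(lines[from:to])
    # per-element 1-based index in molfile atom-block order
    atoms$index <- stats::ave(seq_len(nrow(atoms)), atoms$element,
                              FUN = seq_along)
    role <- role_assignment[role_assignment$slot == k, ]
    if (nrow(role) != 1) stop("no role assignment for molfile slot ", k)
    atoms$metabolite <- role$metabolite_id
    atoms$instance <- role$instance
    atoms$side <- if (k <= ns) "sub" else "prod"
    atoms
  })
  atoms <- do.call(rbind, slot_atoms)

  for (side in c("sub", "prod")) {
    aam <- atoms$aam[atoms$side == side & atoms$aam != 0]
    if (anyDuplicated(aam)) {
      stop("duplicate atom-atom mapping number on ", side,
           " side of reaction ", reaction_id)
    }
  }
  sub <- atoms[atoms$side == "sub" & atoms$aam != 0, ]
  prod <- atoms[atoms$side == "prod" & atoms$aam != 0, ]
  only_one_side <- c(setdiff(sub$aam, prod$aam), setdiff(prod$aam, sub$aam))
  if (length(only_one_side)) {
    stop("mapping number(s) present on only one side of reaction ",
         reaction_id, ": ", paste(only_one_side, collapse = ", "))
  }
  unmapped <- atoms[atoms$aam == 0, c("metabolite", "instance", "element",
                                      "index", "side")]
  if (nrow(unmapped)) {
    msg <- paste0(nrow(unmapped), " unmapped atom(s) in reaction ",
                  reaction_id)
    if (permissive) warning(msg) else stop(msg)
  }
  idx <- match(sub$aam, prod$aam)
  if (any(sub$element != prod$element[idx])) {
    stop("element mismatch within an atom pair of reaction ", reaction_id)
  }
  map <- data.frame(
    sub_met = sub$metabolite, sub_instance = sub$instance,
    element = sub$element, sub_index = sub$index,
    prod_met = prod$metabolite[idx], prod_instance = prod$instance[idx],
    prod_index = prod$index[idx],
    stringsAsFactors = FALSE
  )
  .check_bijection(map, reaction_id)
  attr(map, "unmapped") <- unmapped
  map
}

#' Read atom mappings from a directory of rxnfiles
#'
#' One `.rxn` file per internal reaction; the filename stem is the reaction
#' id. `role_assignments` supplies, per reaction id, the molfile-slot to
#' (metabolite, instance) assignment required by [parse_rxn_v2000()].
#'
#' @param dir directory of `.rxn` files.
#' @param role_assignments named list of role-assignment data frames.
#' @param permissive passed to [parse_rxn_v2000()].
#' @return an `atom_mapping_set`.
#' @export
read_rxn_directory <- function(dir, role_assignments, permissive = FALSE) {
  files <- list.files(dir, pattern = "\\.rxn$", full.names = TRUE)
  maps <- lapply(files, function(f) {
    rid <- sub("\\.rxn$", "", basename(f))
    parse_rxn_v2000(readLines(f), rid, role_assignments[[rid]], permissive)
  })
  names(maps) <- sub("\\.rxn$", "", basename(files))
  atom_mapping_set(maps)
}
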