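#' The BTK kinase-domain region definitions
#'
#' The named sub-structures of the BTK catalytic domain used throughout the
#' analysis, in author (deposited) residue numbering: the global kinase
#' domain, the activation loop (A-loop) and its hydrophobic C-terminal part,
#' the DFG motif at the A-loop N-terminus, the glycine-rich P-loop and the
#' hinge region, plus single-residue anchors for the beta6/beta7-DFG angle
#' (Leu518, Asn526, Asp539) and for Tyr551 exposure.
#'
#' @return A tibble of class `region_set` with columns `region`, `chain`
#'   (`NA` = any single chain), `first`, `last` (inclusive residue numbers).
#' @examples
#' btk_default_regions()
#' @export
btk_default_regions <- function() {
  region_set(tibble(
    region = c("global", "a_loop", "a_loop_cterm", "dfg", "p_loop", "hinge",
               "leu518", "asn526", "asp539", "tyr551"),
    chain = NA_character_,
    first = c(389L, 539L, 550L, 539L, 410L, 475L, 518L, 526L, 539L, 551L),
    last  = c(658L, 559L, 558L, 541L, 415L, 479L, 518L, 526L, 539L, 551L)
  ))
}

#' Construct / validate a region set
#'
#' @param df A data frame with columns `region`, `first`, `last` and
#'   optionally `chain`.
#' @return The validated tibble with class `region_set`.
#' @export
region_set <- function(df) {
  df <- as_tibble(df)
  if (!all(c("region", "first", "last") %in% names(df))) {
    abort("A region set needs columns region, first, last.",
          class = "btkloop_region_error")
  }
  if (!"chain" %in% names(df)) df$chain <- NA_character_
  df$first <- as.integer(df$first)
  df$last <- as.integer(df$last)
  if (any(df$first > df$last)) {
    abort("Region first residue must not exceed last.",
          class = "btkloop_region_error")
  }
  if (anyDuplicated(df$region)) {
    abort("Region names must be unique.", class = "btkloop_region_error")
  }
  df <- df[, c("region", "chain", "first", "last")]
  class(df) <- c("region_set", class(df))
  df
}

#' Read a region set from a YAML config
#'
#' The config maps region names to `[first, last]` pairs or to
#' `{chain: A, first: ..., last: ...}` mappings, so proteins other than BTK
#' can be analysed with the same pipeline.
#'
#' @param path Path to a YAML file.
#' @return A `region_set` tibble.
#' @export
read_regions <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- purrr::imap(y, function(v, nm) {
    if (is.list(v) && !is.null(v$first)) {
      tibble(region = nm, chain = v$chain %||% NA_character_,
             first = as.integer(v$first), last = as.integer(v$last))
    } else {
      v <- as.integer(unlist(v))
      tibble(region = nm, chain = NA_character_,
             first = v[1], last = v[length(v)])
    }
  })
  region_set(dplyr::bind_rows(rows))
}

.region_range <- function(region, regions) {
  if (is.numeric(region) && length(region) %in% 1:2) {
    return(list(first = as.integer(min(region)),
                last = as.integer(max(region)), chain = NA_character_))
  }
  if (is.character(region) && length(region) == 1) {
    hit <- regions[regions$region == region, ]
    if (nrow(hit) != 1) {
      abort(sprintf("Unknown region '%s' (known: %s).", region,
                    paste(regions$region, collapse = ", ")),
            class = "btkloop_region_error")
    }
    return(list(first = hit$first, last = hit$last, chain = hit$chain))
  }
  abort("`region` must be a region name or a numeric residue range.",
        class = "btkloop_region_error")
}

#' Resolve a region to an ordered atom selection
#'
#' Selects atoms of one atom class within a named region (or explicit
#' residue range), in topology order. The backbone class is the
#' `{N, CA, C, O}` convention; `heavy` is every non-hydrogen atom; `all`
#' includes hydrogens. Hetero residues (ligands, ions) are never part of a
#' protein region selection.
#'
#' @param topology An [md_topology()].
#' @param region A region name resolved against `regions`, or a numeric
#'   `c(first, last)` residue range.
#' @param atom_class One of `"CA"`, `"backbone"`, `"heavy"`, `"all"`.
#' @param regions A `region_set`; defaults to [btk_default_regions()].
#' @param chain Chain to select from; defaults to the region's chain, or to
#'   any chain when unspecified.
#' @return An integer vector of atom row indices (strictly increasing) with
#'   attribute `label`.
#' @examples
#' top <- make_toy_topology(5)$topology
#' length(select_atoms(top, c(1, 5), "CA"))
#' @export
select_atoms <- function(topology, region,
                         atom_class = c("CA", "backbone", "heavy", "all"),
                         regions = btk_default_regions(), chain = NULL) {
  atom_class <- match.arg(atom_class)
  rng <- .region_range(region, regions)
  chain <- chain %||% rng$chain
  keep <- !topology$is_het &
    topology$res_seq >= rng$first & topology$res_seq <= rng$last
  if (!is.null(chain) && !is.na(chain)) keep <- keep & topology$chain == chain
  keep <- keep & switch(
    atom_class,
    CA = topology$name == "CA",
    backbone = topology$name %in% c("N", "CA", "C", "O"),
    heavy = topology$element != "H",
    all = TRUE
  )
  idx <- which(keep)
  if (length(idx) == 0) {
    abort(sprintf(
      "Region %s (residues %d-%d, class %s) selects no atoms.",
      if (is.character(region)) region else "range", rng$first, rng$last,
      atom_class), class = "btkloop_empty_selection")
  }
  label <- sprintf("%s/%s", if (is.character(region)) region else
    sprintf("%d-%d", rng$first, rng$last), atom_class)
  structure(idx, label = label)
}
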