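# Conversion between the Genia Event (GE) schema and the Gene Regulation
# Ontology (GRO) schema. GE -> GRO goes through direct concept
# equivalences only. GRO -> GE additionally climbs the GRO is-a hierarchy:
# a concept with no direct equivalence is relabeled to the equivalence of
# its nearest mapped ancestor (GRO being the deeper ontology, many
# specific concepts convert by subsumption, e.g. TranscriptionFactor <
# TranscriptionRegulator < Protein). Concepts with no mapped ancestor are
# dropped, and drops are counted into convertibility statistics.

#' Concept equivalence map between the GE and GRO schemata
#'
#' Loads a two-column (genia, gro) equivalence table. The table is
#' one-to-many for Protein (GRO distinguishes Gene from Protein while the
#' Genia ontology does not); both invert to Protein, and the forward
#' choice is set by `ge_protein_as`. GE concepts in `ignored_ge` have no
#' GRO correspondent and are dropped (with counting) rather than treated
#' as unknown.
#'
#' @param path equivalence TSV with header columns `genia`, `gro`; default
#'   is the shipped benchmark mapping.
#' @param ge_protein_as "protein" or "gene": the GRO target of GE Protein.
#' @param ignored_ge GE concepts to drop silently in the GE -> GRO
#'   direction.
#' @return a `concept_map` list with `ge_to_gro`, `gro_to_ge`,
#'   `ignored_ge`.
#' @export
concept_map <- function(path = system.file("extdata", "ge_gro_mapping.tsv",
                                           package = "geniakb"),
                        ge_protein_as = c("protein", "gene"),
                        ignored_ge = c("Deacetylation", "Ubiquitination")) {
  ge_protein_as <- match.arg(ge_protein_as)
  tb <- read.delim(path, colClasses = "character")
  if (!all(c("genia", "gro") %in% names(tb))) {
    stop_config("equivalence table needs columns genia, gro")
  }
  gro_to_ge <- setNames(tb$genia, tb$gro)
  forward <- tb[tb$genia != "Protein" | tb$gro ==
                  (if (ge_protein_as == "protein") "Protein" else "Gene"), ]
  ge_to_gro <- setNames(forward$gro, forward$genia)
  if (anyDuplicated(names(ge_to_gro))) {
    stop_config("equivalence table maps a GE concept to several GRO concepts beyond Protein")
  }
  structure(list(ge_to_gro = ge_to_gro, gro_to_ge = gro_to_ge,
                 ignored_ge = ignored_ge),
            class = "concept_map")
}

#' Read an is-a hierarchy from a child/parent edge list
#'
#' @param path TSV with header columns `child`, `parent`; default is the
#'   shipped synthetic GRO fragment covering the concepts exercised by the
#'   converter (the full ontology is a drop-in replacement).
#' @return a `concept_hierarchy`: named list child -> character vector of
#'   parents. The edge list must be acyclic.
#' @export
read_hierarchy <- function(path = system.file("extdata",
                                              "gro_isa_synthetic.tsv",
                                              package = "geniakb")) {
  tb <- read.delim(path, colClasses = "character")
  if (!all(c("child", "parent") %in% names(tb))) {
    stop_config("hierarchy needs columns child, parent")
  }
  h <- split(tb$parent, tb$child)
  # cycle check by repeated leaf stripping (Kahn)
  nodes <- unique(c(tb$child, tb$parent))
  edges <- tb
  while (nrow(edges)) {
    roots <- setdiff(nodes, edges$child)
    keep <- !edges$parent %in% roots
    if (all(keep)) stop_config("is-a hierarchy contains a cycle")
    edges <- edges[keep, , drop = FALSE]
    nodes <- unique(c(edges$child, edges$parent))
  }
  structure(h, class = "concept_hierarchy")
}

#' Nearest mapped ancestor of a concept
#'
#' Returns the GE concept for `concept`: its direct equivalence if mapped,
#' otherwise the equivalence of the closest is-a ancestor that is mapped
#' (breadth-first by level; ties at a level broken lexicographically by
#' concept name), or `NA` if no ancestor is mapped. A concept absent from
#' the hierarchy and unmapped yields `NA`, not an error.
#'
#' @param concept a GRO concept label.
#' @param hierarchy a [read_hierarchy()].
#' @param map a [concept_map()] (its `gro_to_ge` direction is used).
#' @return GE concept label or `NA_character_`.
#' @export
#' @examples
#' m <- concept_map(); h <- read_hierarchy()
#' nearest_mapped_ancestor("TranscriptionFactor", h, m) # "Protein"
nearest_mapped_ancestor <- function(concept, hierarchy, map) {
  m <- map$gro_to_ge
  level <- concept
  seen <- character()
  while (length(level)) {
    level <- sort(unique(level))
    mapped <- level[level %in% names(m)]
    if (length(mapped)) return(unname(m[mapped[1]]))
    seen <- c(seen, level)
    level <- setdiff(unlist(hierarchy[intersect(level, names(hierarchy))]),
                     seen)
  }
  NA_character_
}

# Relabel all annotation in a document through label_fun (label -> new
# label or NA = drop). Trigger entities follow their event's type; other
# entities map independently. Dropping removes the annotation, removes
# arguments that pointed at it (recursively through dropped events), and
# counts into the statistics. An event counts as convertible iff its own
# type maps; losing arguments does not reclassify it.
relabel_document <- function(doc, label_fun) {
  ents <- doc$entities
  evs <- doc$events
  trigger_ids <- unique(evs$trigger_id)
  is_trigger <- ents$id %in% trigger_ids

  ent_new <- ifelse(is_trigger, NA_character_,
                    map_chr(ents$type, label_fun))
  ev_new <- if (nrow(evs)) map_chr(evs$type, label_fun) else character()

  keep_ev <- !is.na(ev_new)
  dropped_ids <- c(ents$id[!is_trigger & is.na(ent_new)], evs$id[!keep_ev])

  # triggers inherit the (converted) type of a surviving event they anchor
  for (i in which(is_trigger)) {
    owners <- which(evs$trigger_id == ents$id[i] & keep_ev)
    ent_new[i] <- if (length(owners)) ev_new[owners[1]] else NA_character_
  }

  keep_ent <- !is.na(ent_new)
  new_ents <- ents[keep_ent, ]
  new_ents$type <- ent_new[keep_ent]

  new_evs <- evs[keep_ev, ]
  if (nrow(new_evs)) {
    new_evs$type <- ev_new[keep_ev]
    new_evs$args <- map(new_evs$args, function(a) {
      a <- a[!a$target %in% dropped_ids, , drop = FALSE]
      # re-suffix coordination after removals so labels stay canonical
      if (nrow(a)) {
        base <- role_base(a$role)
        idx <- stats::ave(seq_along(base), base, FUN = seq_along)
        a$role <- ifelse(idx == 1, base, paste0(base, idx))
      }
      a
    })
  }

  ent_kept <- sum(keep_ent & !is_trigger)
  stats <- tibble(
    kind = c("entities", "events"),
    convertible = c(ent_kept, sum(keep_ev)),
    dropped = c(sum(!is_trigger) - ent_kept, sum(!keep_ev))
  )
  stats <- structure(stats, class = c("kb_conversion_stats", class(stats)))

  list(
    doc = ast_document(doc$text, new_ents, new_evs, ref = doc$ref,
                       extra = doc$extra),
    stats = stats
  )
}

#' Convert a GE-schema document to the GRO schema
#'
#' Entity and event types are relabeled through the direct equivalences
#' (Binding -> BindingToProtein, etc.; GE Protein goes to GRO Protein or
#' Gene per the map's configuration). GE concepts with no GRO
#' correspondent (by default Deacetylation and Ubiquitination) are dropped
#' and counted; arguments pointing at dropped annotation are removed.
#'
#' @param doc an [ast_document()] using GE concept labels.
#' @param map a [concept_map()].
#' @param strict error on a GE concept that is neither mapped nor declared
#'   ignored (TRUE), or drop it with counting (FALSE)?
#' @return list with elements `doc` (converted document) and `stats` (a
#'   `kb_conversion_stats` tibble).
#' @export
convert_ge_to_gro <- function(doc, map = concept_map(), strict = TRUE) {
  relabel_document(doc, function(label) {
    if (label %in% names(map$ge_to_gro)) return(unname(map$ge_to_gro[label]))
    if (label %in% map$ignored_ge) return(NA_character_)
    if (strict) stop_conversion(sprintf("unknown GE concept: %s", label))
    NA_character_
  })
}

#' Convert a GRO-schema document to the GE schema
#'
#' Each annotation is relabeled to the GE equivalence of its
#' [nearest_mapped_ancestor()]; concepts with no mapped ancestor (e.g. the
#' organism/tissue/chemical branches) are dropped and counted.
#'
#' @param doc an [ast_document()] using GRO concept labels.
#' @param map a [concept_map()].
#' @param hierarchy a [read_hierarchy()].
#' @return list with elements `doc` and `stats`, as in
#'   [convert_ge_to_gro()].
#' @export
convert_gro_to_ge <- function(doc, map = concept_map(),
                              hierarchy = read_hierarchy()) {
  relabel_document(doc, function(label) {
    nearest_mapped_ancestor(label, hierarchy, map)
  })
}

#' Sum convertibility statistics over documents
#'
#' @param stats_list list of `kb_conversion_stats` tibbles.
#' @return one `kb_conversion_stats` tibble.
#' @export
combine_conversion_stats <- function(stats_list) {
  out <- list_rbind(map(stats_list, as_tibble)) |>
    group_by(kind) |>
    summarise(convertible = sum(convertible), dropped = sum(dropped),
              .groups = "drop") |>
    arrange(match(kind, c("entities", "events")))
  structure(out, class = c("kb_conversion_stats", class(out)))
}

#' Format convertibility statistics
#'
#' Counts with thousands separators and percentages at one decimal
#' (half-up), in the layout of the benchmark's conversion-rate table. A
#' row whose total is zero renders 0.0% for both shares, with a warning.
#'
#' @param stats a `kb_conversion_stats` tibble (see [convert_ge_to_gro()]),
#'   or a list of them (summed first).
#' @return character vector of lines.
#' @export
#' @examples
#' s <- tibble::tibble(kind = c("entities", "events"),
#'                     convertible = c(6449L, 3436L),
#'                     dropped = c(125L, 280L))
#' conversion_stats_report(s)
conversion_stats_report <- function(stats) {
  if (!is.data.frame(stats)) stats <- combine_conversion_stats(stats)
  total <- stats$convertible + stats$dropped
  if (any(total == 0)) {
    warn("conversion statistics over zero annotations",
         class = "geniakb_degenerate_stats")
  }
  pct <- function(n) {
    sprintf("%.1f%%", round_half_up(ifelse(total == 0, 0, 100 * n / total), 1))
  }
  header <- "kind\toutcome\tcount (share)"
  policy <- "# an event is convertible iff its own type maps; argument loss does not reclassify it"
  c(policy, header,
    sprintf("%s\tConvertible\t%s (%s)", stats$kind,
            format_count(stats$convertible), pct(stats$convertible)),
    sprintf("%s\tNon-convertible\t%s (%s)", stats$kind,
            format_count(stats$dropped), pct(stats$dropped)))
}
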