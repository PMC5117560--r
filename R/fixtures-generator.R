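# Synthetic planted-moiety network generator. Moieties are modelled as
# indivisible tokens with fixed element compositions. Each moiety starts in a
# private precursor metabolite holding exactly one instance; reactions pool
# the tokens of one or two substrate metabolites and repartition them into
# one or two products, so every reaction conserves every token by
# construction. At most one instance of a moiety per metabolite type is
# allowed, which keeps each planted moiety's instance graph connected and
# (together with the private precursor rows) makes the planted moiety
# vectors pairwise distinct, so identification recovers the ground-truth
# moiety matrix exactly, up to column permutation.

#' Generate a random metabolic network with planted conserved moieties
#'
#' @param seed integer seed; the construction is deterministic under it.
#' @param n_moieties number of moieties to plant.
#' @param size_range integer range (min, max) of atoms per moiety
#'   composition.
#' @param n_metabolites approximate number of metabolites (at least
#'   `2 * n_moieties`; compound metabolites are added until reached).
#' @param n_reactions number of internal reactions to attempt.
#' @return a fixture list with `network`, `mappings`, and `expected`
#'   containing the ground-truth moiety matrix `L` and `compositions`.
#' @export
planted_moiety_generator <- function(seed, n_moieties = 4,
                                     size_range = c(1, 6),
                                     n_metabolites = 10, n_reactions = 8) {
  if (n_moieties < 1 || n_metabolites < 2 * n_moieties) {
    stop("infeasible parameters: need n_metabolites >= 2 * n_moieties")
  }
  set.seed(seed)
  elements <- c("C", "H", "N", "O", "P", "S")
  compositions <- lapply(seq_len(n_moieties), function(k) {
    size <- sample(size_range[1]:size_range[2], 1)
    picked <- sample(elements, min(size, sample(1:3, 1)), replace = FALSE)
    counts <- as.vector(stats::rmultinom(1, size, rep(1, length(picked))))
    stats::setNames(counts, picked)[counts > 0]
  })

  # metabolite types as moiety-index sets; start from private precursors
  types <- lapply(seq_len(n_moieties), function(k) k)
  names(types) <- sprintf("P%02d", seq_len(n_moieties))
  reactions <- list()   # each: list(subs, prods, moves = data.frame)
  new_id <- function() sprintf("X%02d", length(types) - n_moieties + 1)

  type_with <- function(tokens) {
    key <- paste(sort(tokens), collapse = ",")
    hits <- names(types)[vapply(types, function(t) {
      paste(sort(t), collapse = ",") == key
    }, logical(1))]
    if (length(hits)) hits[1] else NA_character_
  }

  for (r in seq_len(n_reactions)) {
    ok <- FALSE
    for (attempt in 1:25) {
      types_snapshot <- types  # roll back types created by a failed attempt
      n_sub <- if (length(types) > 1) sample(1:2, 1) else 1
      subs <- sample(names(types), n_sub)
      pool <- unlist(types[subs], use.names = FALSE)
      if (anyDuplicated(pool) || length(pool) == 0) next
      # repartition the pooled tokens into 1-2 products
      n_prod <- if (length(pool) > 1) sample(1:2, 1) else 1
      assign <- if (n_prod == 1) rep(1, length(pool)) else {
        a <- sample(1:2, length(pool), replace = TRUE)
        if (length(unique(a)) == 1) a[sample(length(a), 1)] <- 3 - a[1]
        a
      }
      prod_tokens <- split(pool, assign)
      prods <- vapply(prod_tokens, function(tok) {
        hit <- type_with(tok)
        if (!is.na(hit)) hit else {
          id <- new_id()
          types[[id]] <<- sort(tok)
          id
        }
      }, character(1))
      if (anyDuplicated(prods) || any(prods %in% subs)) {
        types <- types_snapshot
        next
      }
      moves <- do.call(rbind, lapply(seq_along(prods), function(g) {
        data.frame(moiety = unname(prod_tokens[[g]]),
                   sub = vapply(prod_tokens[[g]], function(k) {
                     subs[vapply(types[subs], function(t) k %in% t,
                                 logical(1))][1]
                   }, character(1), USE.NAMES = FALSE),
                   prod = unname(prods[g]), stringsAsFactors = FALSE)
      }))
      reactions[[length(reactions) + 1]] <-
        list(subs = subs, prods = unname(prods), moves = moves)
      ok <- TRUE
      break
    }
    if (!ok) next
    if (length(types) >= n_metabolites) break
  }
  if (length(reactions) == 0) stop("infeasible parameters: no reaction built")

  met_ids <- names(types)
  formulas <- lapply(types, function(tok) {
    f <- Reduce(function(a, b) {
      all_e <- union(names(a), names(b))
      out <- stats::setNames(numeric(length(all_e)), all_e)
      out[names(a)] <- out[names(a)] + a
      out[names(b)] <- out[names(b)] + b
      out
    }, compositions[tok])
    f[.element_order(names(f))]
  })
  mets <- data.frame(id = met_ids, name = met_ids, charge = 0,
                     stringsAsFactors = FALSE)

  rxn_ids <- sprintf("R%02d", seq_along(reactions))
  stoich <- stats::setNames(lapply(reactions, function(rx) {
    stats::setNames(c(rep(-1, length(rx$subs)), rep(1, length(rx$prods))),
                    c(rx$subs, rx$prods))
  }), rxn_ids)
  # exchange sinks for a random metabolite subset (always >= 1)
  sink_mets <- sample(met_ids, max(1, ceiling(length(met_ids) / 3)))
  ex_ids <- sprintf("E%02d", seq_along(sink_mets))
  stoich <- c(stoich, stats::setNames(
    lapply(sink_mets, function(id) stats::setNames(-1, id)), ex_ids))
  rxns <- data.frame(
    id = c(rxn_ids, ex_ids),
    kind = c(rep("internal", length(rxn_ids)),
             rep("exchange", length(ex_ids))),
    stringsAsFactors = FALSE
  )
  net <- metabolic_network(mets, rxns, stoich, formulas)

  # atom layout: within a metabolite, tokens in ascending moiety order, each
  # occupying consecutive per-element indices
  offsets <- lapply(types, function(tok) {
    tok <- sort(tok)
    off <- list()
    cursor <- stats::setNames(numeric(0), character(0))
    for (k in tok) {
      comp <- compositions[[k]]
      ofs <- vapply(names(comp), function(e) {
        if (is.na(cursor[e])) cursor[e] <<- 0
        o <- cursor[[e]]
        cursor[e] <<- cursor[[e]] + comp[[e]]
        o
      }, numeric(1))
      off[[as.character(k)]] <- ofs
    }
    off
  })
  maps <- stats::setNames(lapply(reactions, function(rx) {
    do.call(rbind, lapply(seq_len(nrow(rx$moves)), function(i) {
      k <- rx$moves$moiety[i]
      comp <- compositions[[k]]
      so <- offsets[[rx$moves$sub[i]]][[as.character(k)]]
      po <- offsets[[rx$moves$prod[i]]][[as.character(k)]]
      do.call(rbind, lapply(names(comp), function(e) {
        .map_rows(sub_met = rx$moves$sub[i], element = e,
                  sub_index = so[[e]] + seq_len(comp[[e]]),
                  prod_met = rx$moves$prod[i],
                  prod_index = po[[e]] + seq_len(comp[[e]]))
      }))
    }))
  }), rxn_ids)

  L <- matrix(0L, length(met_ids), n_moieties,
              dimnames = list(met_ids, sprintf("G%02d", seq_len(n_moieties))))
  for (id in met_ids) L[id, types[[id]]] <- 1L
  list(network = net,
       mappings = atom_mapping_set(maps),
       expected = list(L = L, compositions = compositions))
}
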