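## Dollo (irreversible-loss) reconstruction on rooted, possibly
## multifurcating taxonomy trees: a trait present at the root can only be
## lost, never regained, so the minimum-loss labeling marks a node present
## exactly when some informative descendant tip is present, and each
## maximal all-absent subtree under a present parent is one independent
## loss event.

#' Read a rooted taxonomy tree from Newick text or a file
#'
#' Branch lengths are ignored; polytomies and internal (clade) labels are
#' preserved.
#'
#' @param x Newick string (must end in `;`) or path to a Newick file.
#' @return An `ape` `phylo` tree.
#' @export
read_taxon_tree <- function(x) {
  tr <- if (length(x) == 1L && !grepl(";", x) && file.exists(x))
    ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) abort("could not parse Newick (unbalanced parentheses?)")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    abort(sprintf("duplicate tip labels: %s", paste(unique(dup), collapse = ", ")))
  tr
}

## node label helper: tips use tip.label, internals node.label or "node_<id>"
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl <- ifelse(nzchar(nl), nl, paste0("node_", ntip + seq_len(tree$Nnode)))
  c(tree$tip.label, nl)
}

## children list indexed by node id
children_of <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge)))
    ch[[tree$edge[k, 1]]] <- c(ch[[tree$edge[k, 1]]], tree$edge[k, 2])
  ch
}

root_of <- function(tree) setdiff(unique(tree$edge[, 1]), tree$edge[, 2])

#' Dollo reconstruction of one presence/absence trait on a tree
#'
#' Tip states are `"present"`, `"absent"` or `"unknown"` (missing data; a
#' logical vector with `NA` as unknown also works). An internal node is
#' reconstructed present iff any informative descendant tip is present. A
#' loss event is recorded on every edge whose parent is present and whose
#' child subtree contains no present tip but at least one absent tip;
#' subtrees containing only unknown tips inherit the parental state and
#' contribute no losses. With no present tip anywhere the trait is absent
#' throughout and no losses are counted. On a polytomy each child subtree
#' is evaluated independently, so k all-absent children under a present
#' parent yield k losses — the conservative (maximal) count for an
#' unresolved node.
#'
#' @param tree `phylo` tree (rooted; polytomies allowed).
#' @param tip_states Named character (`present`/`absent`/`unknown`) or
#'   logical (`NA` = unknown) vector covering every tip.
#' @param trait Trait name carried through to outputs.
#' @return A `dollo_loss` object: `trait`, per-node `node_state`,
#'   `loss_edges` (labels of the child nodes of loss edges), `n_losses`,
#'   `root_state` (see [infer_root_state()]), `tips_unknown`, `tree`.
#' @export
dollo_reconstruct <- function(tree, tip_states, trait = "trait") {
  st <- normalize_states(tree, tip_states)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  ch <- children_of(tree)
  root <- root_of(tree)
  labs <- node_labels(tree)

  has_present <- logical(n_all)
  informative <- logical(n_all) # any non-unknown tip below (or at) the node
  po <- rev(postorder_nodes(tree)) # tips before parents
  for (v in po) {
    if (v <= ntip) {
      has_present[v] <- st[v] == "present"
      informative[v] <- st[v] != "unknown"
    } else {
      has_present[v] <- any(has_present[ch[[v]]])
      informative[v] <- any(informative[ch[[v]]])
    }
  }

  any_present <- has_present[root]
  state <- character(n_all)
  loss_child <- integer(0)
  # preorder: assign states, record losses
  stack <- root
  state[root] <- if (any_present) "present" else "absent"
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in ch[[v]]) {
      if (!informative[w]) {
        state[w] <- state[v] # unknown-only subtree inherits, no loss
      } else if (has_present[w]) {
        state[w] <- "present"
      } else {
        state[w] <- "absent"
        if (state[v] == "present") loss_child <- c(loss_child, w)
      }
      if (w > ntip) stack <- c(stack, w)
    }
  }

  structure(list(
    trait = trait,
    node_state = setNames(state, labs),
    loss_edges = labs[loss_child],
    n_losses = length(loss_child),
    root_state = infer_root_state(tree, tip_states),
    tips_unknown = tree$tip.label[st[seq_len(ntip)] == "unknown"],
    tree = tree
  ), class = "dollo_loss")
}

normalize_states <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  if (is.logical(tip_states))
    tip_states <- ifelse(is.na(tip_states), "unknown",
                         ifelse(tip_states, "present", "absent"))
  if (is.null(names(tip_states)) && length(tip_states) == ntip)
    names(tip_states) <- tree$tip.label
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    abort(sprintf("tips without state: %s", paste(missing, collapse = ", ")))
  st <- tip_states[tree$tip.label]
  bad <- !st %in% c("present", "absent", "unknown")
  if (any(bad)) abort("tip states must be present/absent/unknown")
  st
}

## parent-before-child ordering of all nodes (preorder); reversed = postorder
postorder_nodes <- function(tree) {
  ch <- children_of(tree)
  root <- root_of(tree)
  out <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, ch[[v]])
  }
  out
}

#' Infer the root (ancestral) state of a trait under irreversibility
#'
#' Because a trait is gained once and never regained, presence in tips
#' under two or more distinct children of the root forces presence at the
#' root itself (the LECA-style inference). Presence confined to a single
#' root child's subtree only shows the trait originated (or survived)
#' within that subtree; no presence at all means absent.
#'
#' @inheritParams dollo_reconstruct
#' @return `"present_at_root"`, `"origin_within_tree"` or `"absent"`.
#' @export
infer_root_state <- function(tree, tip_states) {
  st <- normalize_states(tree, tip_states)
  ntip <- length(tree$tip.label)
  ch <- children_of(tree)
  root <- root_of(tree)
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(ch[[v]], tips_below))
  }
  n_children_with_present <- sum(vapply(ch[[root]], function(w) {
    any(st[tips_below(w)] == "present")
  }, logical(1)))
  if (n_children_with_present >= 2) "present_at_root"
  else if (n_children_with_present == 1) "origin_within_tree"
  else "absent"
}

#' Count independent losses per component and per complex
#'
#' Builds per-trait tip states from a tier matrix (presence = any positive
#' tier H/M/L/P) and reconstructs losses for every component plus the two
#' complexes (TORC1 keyed on RAPTOR, TORC2 on RICTOR). Under the
#' `"missing"` unknown policy, an ABS call in a species with completeness
#' below `busco_low_threshold` that was never put through read rescue is
#' treated as missing data rather than true absence, so poor proteomes
#' cannot create spurious losses.
#'
#' @param tiers Tier tibble (complete matrix).
#' @param tree Taxonomy tree whose tips include all matrix species.
#' @param unknown_policy `"absent"` (trust all ABS calls) or `"missing"`.
#' @param metadata Tibble with `species` and `completeness` (needed for the
#'   `"missing"` policy).
#' @param busco_low_threshold Completeness cutoff for the missing policy.
#' @return List: `reconstructions` (named list of `dollo_loss`) and
#'   `summary` tibble (`trait`, `n_losses`, `root_state`, `loss_edges`).
#' @export
count_losses_per_trait <- function(tiers, tree,
                                   unknown_policy = c("absent", "missing"),
                                   metadata = NULL,
                                   busco_low_threshold = 0.70) {
  unknown_policy <- match.arg(unknown_policy)
  extra <- setdiff(unique(tiers$species), tree$tip.label)
  if (length(extra))
    abort(sprintf("species not in tree: %s", paste(extra, collapse = ", ")))
  x <- tiers
  if (unknown_policy == "missing") {
    if (is.null(metadata)) abort("`metadata` needed for the missing policy")
    x <- x |> left_join(metadata |> select("species", "completeness"),
                        by = "species")
    x$unknown <- x$tier == "ABS" & x$completeness < busco_low_threshold &
      !has_flag(x$flags, "rescue_attempted")
  } else x$unknown <- FALSE
  x$state <- ifelse(x$unknown, "unknown",
                    ifelse(x$tier %in% c("H", "M", "L", "P"),
                           "present", "absent"))
  traits <- c(setNames(as.list(unique(x$component)), unique(x$component)),
              list(TORC1 = "RAPTOR", TORC2 = "RICTOR"))
  # species may be a subset of the tips: missing tips are unknown
  recs <- purrr::imap(traits, function(comp, nm) {
    sub <- x |> filter(.data$component == comp)
    st <- setNames(rep("unknown", length(tree$tip.label)), tree$tip.label)
    st[sub$species] <- sub$state
    dollo_reconstruct(tree, st, trait = nm)
  })
  summary <- purrr::map(recs, glance) |> bind_rows()
  list(reconstructions = recs, summary = summary)
}

#' Write a tree annotated with reconstructed node states
#'
#' Node and tip labels gain a `|present` / `|absent` suffix so the
#' reconstruction travels with the Newick file.
#'
#' @param recon A `dollo_loss` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(recon, path) {
  tr <- recon$tree
  labs <- node_labels(tr)
  ann <- paste0(labs, "|", recon$node_state)
  ntip <- length(tr$tip.label)
  tr$tip.label <- ann[seq_len(ntip)]
  tr$node.label <- ann[ntip + seq_len(tr$Nnode)]
  ape::write.tree(tr, file = path)
  invisible(path)
}

## broom-style accessors ----------------------------------------------------

#' @export
print.dollo_loss <- function(x, ...) {
  cat(sprintf("<dollo_loss> trait %s: %d independent loss event(s), root %s\n",
              x$trait, x$n_losses, x$root_state))
  if (x$n_losses)
    cat("  loss edges (child labels):", paste(x$loss_edges, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Dollo reconstruction into one row per node
#' @param x A `dollo_loss` object.
#' @param ... Unused.
#' @return Tibble: `node`, `label`, `is_tip`, `state`, `loss_edge`.
#' @method tidy dollo_loss
#' @export
tidy.dollo_loss <- function(x, ...) {
  labs <- node_labels(x$tree)
  ntip <- length(x$tree$tip.label)
  tibble(node = seq_along(labs), label = labs,
         is_tip = seq_along(labs) <= ntip,
         state = unname(x$node_state),
         loss_edge = labs %in% x$loss_edges)
}

#' One-row summary of a Dollo reconstruction
#' @param x A `dollo_loss` object.
#' @param ... Unused.
#' @return Tibble with `trait`, `n_losses`, `root_state`, `n_tips_present`,
#'   `n_tips_absent`, `n_tips_unknown`, `loss_edges` (comma-collapsed).
#' @method glance dollo_loss
#' @export
glance.dollo_loss <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  tip_states <- x$node_state[seq_len(ntip)]
  tip_states[x$tree$tip.label %in% x$tips_unknown] <- "unknown"
  tibble(trait = x$trait, n_losses = x$n_losses, root_state = x$root_state,
         n_tips_present = sum(tip_states == "present"),
         n_tips_absent = sum(tip_states == "absent"),
         n_tips_unknown = length(x$tips_unknown),
         loss_edges = paste(x$loss_edges, collapse = ","))
}
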