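#' Bundled 12-taxon dated tree
#'
#' The default study phylogeny: four great-ape outgroups (orangutan,
#' gorilla, bonobo, chimpanzee) above a human clade of eight
#' representatives of major Y-chromosomal haplogroups (A0, A1, B, C, E,
#' J, N, R), with the focal node at the MRCA of the human tips. Node
#' ages are representative published-scale divergence-time estimates in
#' years before present (primate splits 15.2, 8.6 and 6.7 Mya,
#' bonobo-chimpanzee 1.7 Mya; human MRCA 235 kya descending to the
#' N/R split at 36.8 kya).
#'
#' @return A `dated_tree` with 12 tips, 11 internal nodes, focal node
#'   `human_mrca`.
#' @examples
#' tr <- default_dated_tree()
#' tr
#' @export
default_dated_tree <- function() {
  newick <- paste0(
    "(orangutan,(gorilla,((bonobo,chimpanzee)pan_mrca,",
    "(A0,(A1,(B,(C,(E,(J,(N,R)k_mrca)hijk_mrca)de_mrca)ct_mrca)bt_mrca)",
    "a1t_mrca)human_mrca)hominini_mrca)homininae_mrca)root;")
  ages <- c(root = 15.2e6,
            homininae_mrca = 8.6e6,
            hominini_mrca = 6.7e6,
            pan_mrca = 1.7e6,
            human_mrca = 235000,
            a1t_mrca = 161000,
            bt_mrca = 130000,
            ct_mrca = 88000,
            de_mrca = 76000,
            hijk_mrca = 47600,
            k_mrca = 36800)
  read_dated_tree(newick, ages, "human_mrca")
}

#' Human tip labels of the bundled tree
#'
#' @return Character vector of the eight ingroup (human haplogroup) tip
#'   labels of [default_dated_tree()].
#' @export
default_human_tips <- function() c("A0", "A1", "B", "C", "E", "J", "N", "R")
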