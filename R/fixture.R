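## The built-in odor-network fixture: a curated reconstruction of the
## 16-gene interaction network, the published chemotaxis table, and the
## pathway-position categories. See inst/extdata/README.md for provenance
## and curation notes.

#' Built-in odor-network fixture
#'
#' Returns the 16-gene *C. elegans* volatile-odor network fixture: a curated
#' reconstruction of the interaction map (16 edges; diameter 5,
#' characteristic path length 2.825, mean neighbors 2), every published
#' chemotaxis record for its mutants (wildtype references, odortaxis
#' deficits and long-term-adaptation responses), and the three
#' pathway-position categories (6 class-1 regulators, 6 class-2 regulators,
#' 4 actuators).
#'
#' @return List with elements `network` (an [interaction_network]),
#'   `chemotaxis` (data frame of chemotaxis records) and `categories`
#'   (named character vector gene -> pathway category).
#' @export
#' @examples
#' fx <- make_odor_fixture()
#' network_summary(fx$network)
make_odor_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "odornet",
                                  mustWork = TRUE)
  net <- read_edge_list(path("odor_network.tsv"))
  chem <- read_chemotaxis_table(path("odor_chemotaxis.tsv"))
  cats <- utils::read.delim(path("odor_categories.tsv"),
                            stringsAsFactors = FALSE)
  list(network = net,
       chemotaxis = chem,
       categories = stats::setNames(cats$category, cats$gene))
}
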