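# Shared fixtures built in code.

# A small hand-built ontology exercising multi-parent levels, part_of
# exclusion, childless promotion and an obsolete term.
toy_obo <- function() c(
  "format-version: 1.2",
  "",
  "[Term]",
  "id: GO:0003674",
  "name: molecular_function",
  "namespace: molecular_function",
  "",
  "[Term]",
  "id: GO:0000001",
  "name: alpha activity",
  "namespace: molecular_function",
  "is_a: GO:0003674",
  "",
  "[Term]",
  "id: GO:0000002",
  "name: beta activity",
  "namespace: molecular_function",
  "is_a: GO:0003674",
  "",
  "[Term]",
  "id: GO:0000003",
  "name: gamma activity",          # level {2} via alpha
  "namespace: molecular_function",
  "is_a: GO:0000001",
  "",
  "[Term]",
  "id: GO:0000004",
  "name: delta activity",          # levels {2, 3}: parents beta (1), gamma (2)
  "namespace: molecular_function",
  "is_a: GO:0000002",
  "is_a: GO:0000003",
  "",
  "[Term]",
  "id: GO:0000005",
  "name: epsilon activity",        # part_of only: no level
  "namespace: molecular_function",
  "relationship: part_of GO:0000001",
  "",
  "[Term]",
  "id: GO:0000006",
  "name: zeta activity",           # childless level-1 term (promotion case)
  "namespace: molecular_function",
  "is_a: GO:0003674",
  "",
  "[Term]",
  "id: GO:0000007",
  "name: eta activity",
  "namespace: molecular_function",
  "alt_id: GO:0000099",
  "is_a: GO:0000004",
  "",
  "[Term]",
  "id: GO:0000008",
  "name: theta activity",
  "namespace: molecular_function",
  "is_obsolete: true",
  "is_a: GO:0000001")

toy_dag <- function() parse_obo(toy_obo())

# Three-line GAF with an aspect-P row, a NOT row and a duplicate.
toy_gaf <- function() {
  row <- function(gene, qual, term, aspect, ev = "IEA")
    paste(c("SYNT", gene, gene, qual, term, "SYNT:1", ev, "", aspect,
            "x", "", "protein", "taxon:1", "20091101", "SYNT", "", ""),
          collapse = "\t")
  c("!gaf-version: 2.2",
    row("gene1", "enables", "GO:0000007", "F"),
    row("gene1", "enables", "GO:0000007", "F", ev = "IDA"),  # dup, diff code
    row("gene2", "NOT|enables", "GO:0000007", "F"),
    row("gene3", "enables", "GO:0000003", "F"),
    row("gene4", "involved_in", "GO:0000003", "P"))
}

# Fixture set of 7-leaf rooted trees for GSI contract checks.
seven_leaf_trees <- function() {
  lapply(c("(((a,b),(c,d)),((e,f),g));",
           "((((((a,b),c),d),e),f),g);",
           "(((a,(b,c)),(d,(e,f))),g);"),
         function(s) ape::read.tree(text = s))
}
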