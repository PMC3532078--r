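# dtmsim

Simulation of DNA multiple sequence alignments evolving under **discrete-time
Markov models** on phylogenetic trees — directly from probability substitution
matrices, with no rate-matrix (continuous-time) structure imposed.

Mainstream simulators assume a stationary, time-reversible continuous-time
process: one rate matrix `Q` and edge matrices `exp(tQ)`. `dtmsim` targets the
complementary setting needed to stress-test reconstruction and model-selection
methods: each edge `e` carries its own arbitrary row-stochastic matrix `P_e`
(nonhomogeneous), and under the strand symmetric (SSM) and general Markov
(GMM) classes the base composition may drift along the tree (nonstationary).

The core problem the package solves is *branch-length-constrained matrix
sampling*. Branch lengths use the log-determinant convention

```
l_e = -1/4 · log det(P_e)        ⇔        det(P_e) = exp(-4 l_e)
```

so for every edge of the input Newick tree a random matrix of the requested
model class — discrete-time JC69, K80, K81, SSM or GMM — is drawn whose
determinant equals `exp(-4 l_e)` exactly (closed form for JC69; eigenvalue
parameterisation for K80/K81; identity-mixture bisection for SSM/GMM), and is
then converted by an allowable row permutation to **DLC** form (diagonal
largest in every column, strictly), which makes the generating parameters
identifiable from the joint leaf distribution. A root sequence drawn from the
model's root distribution is evolved site-independently down the tree.

Outputs are a FASTA alignment and a plain-text parameter file recording the
seed, root distribution and every edge matrix (17 significant digits, exactly
re-parseable) in a canonical edge order: terminal edges first in leaf
appearance order, then internal edges top-down from the root.

See the methods vignette
(`vignettes/simulating-discrete-time-markov-alignments.Rmd`) for the samplers,
the DLC/identifiability rationale and the design choices.

## Worked example

The 5-taxon tree with branch lengths (0.01, 0.2, 0.3, 0.5, 0.4, 0.7), model
K81, 10000 sites:

```r
library(dtmsim)
tree <- parseNewick(
  "((species1:0.01,species2:0.2,species3:0.3):0.5,species4:0.4,species5:0.7);")
sim <- simulateAlignment(tree, "k81", L = 10000, seed = 1)
alignment(sim)
#> DNAStringSet object of length 5:
#>     width seq                                               names
#> [1] 10000 ATACTGAAAAGAGCGTGGGTGAT...TGATAATGCCGTGTTTTCCGCAA species1
#> [2] 10000 ATCCTGAAAATAGCGTGGATGGT...TCATAATGCCGTGTTTTTCGAAA species2
#> [3] 10000 TCACTGGAAGGAGCATGGATGAT...TGATAATGCTGTATCTTCCGCAA species3
#> [4] 10000 ATGGTGATATTTCCTTAAGCCCG...TGTTACTGCCGAAATAAAGGGCA species4
#> [5] 10000 AGGTCAATGCTGCACTGGGCCCG...TCTTGTCTACGCAGTCACGGACG species5
```

Every sampled matrix reproduces its edge length through its determinant:

```r
vapply(edgeMatrices(simulationRecord(sim)), logdetBranchLength, numeric(1))
#>                     species1                     species2
#>                         0.01                         0.20
#>                     species3                     species4
#>                         0.30                         0.40
#>                     species5 (species1,species2,species3)
#>                         0.70                         0.50
```

The matrix of the internal edge (length 0.5, so det = exp(-2)) is a K81
matrix, DLC, with the Kimura 3-parameter shape:

```r
as.matrix(edgeMatrices(simulationRecord(sim))[[6]])
#>           A         C         G         T
#> A 0.6435704 0.1374711 0.0475074 0.1714511
#> C 0.1374711 0.6435704 0.1714511 0.0475074
#> G 0.0475074 0.1714511 0.6435704 0.1374711
#> T 0.1714511 0.0475074 0.1374711 0.6435704
```

Simulated data close the loop: the paralinear (log-det) distance between two
leaves estimates the path length between them (here 0.2 + 0.3):

```r
two <- simulateAlignment("(A:0.2,B:0.3);", "k81", L = 500000, seed = 606)
paralinearDistance(empiricalJoint(two, "A", "B"))
#> [1] 0.5020299
```

The same simulation from a shell (tree file in, FASTA + parameter file out):

```sh
Rscript inst/scripts/dtmsim tree.txt data.fa 10000 k81 --seed 1
```

`readParams("data.fa.params.txt")` reconstructs every matrix to full double
precision.

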