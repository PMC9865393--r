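---
title: "Generative molecular design with selfgen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative molecular design with selfgen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a handful of molecules with known activity against a receptor
family (here the RORγ nuclear-receptor domains 7NPC, 7NP5 and 7KXD are
the worked example), we want plausible new drug-like molecules in their
chemical neighbourhood, ranked by drug-likeness, synthesizability and
predicted binding. The chemical space of small drug-like molecules
(10^23--10^60 by common estimates) cannot be enumerated -- the bundled
`systematic_search_size()` utility makes that concrete: a brute-force
scan of a 10^3 Å^3 pocket at 0.5 Å translational and 10° angular
resolution for a ligand with four rotatable bonds already requires on
the order of 6 × 10^14 energy evaluations, i.e. about nineteen thousand
years at a thousand evaluations per second. Instead, a recurrent
autoencoder learns a continuous latent representation of molecules, and
new candidates are sampled by perturbing the latent states of known
actives.

## Molecular representation

Everything the sequence model sees is derived from SELFIES, a molecular
string grammar in which *every* well-formed token string derives a
chemically valid molecule. This is the property that makes naive latent
sampling workable: a decoded string can be malformed SMILES, but it
cannot be malformed SELFIES.

The codec in `R/selfies.R` is the package's own implementation of this
idea, a self-contained dialect covering neutral organic molecules over
C, N, O, S, P and the halogens:

* atom tokens `[X]`, `[=X]`, `[#X]` request a bond of order 1--3 to the
  current atom, capped by both atoms' remaining valence
  (C 4, N 3, O 2, S 6, P 5, halogens 1);
* `[Branch1]`/`[Branch2]` open a side chain whose token length is given
  by one or two following index symbols;
* `[Ring1]`/`[Ring2]` (with `[=Ring1]` etc. for multiple bonds) close a
  ring to a previously derived atom;
* a token that cannot apply in the current state is skipped, and a
  saturated chain terminates the derivation -- which is exactly why no
  string can fail to decode.

Hydrogens are implicit under the standard SMILES valence-fill rules, and
the encoder verifies on round trip that the hydrogen count survives
re-parsing; charged, isotopic, radical and exotic-valence species are
rejected as unencodable rather than encoded wrongly. Stereochemistry is
deliberately erased: all SMILES are canonicalised to their *generic*
form first (`canonicalize_generic()`), which shrinks the character set
the model must learn. The contract tested throughout is that
`selfies_to_smiles(smiles_to_selfies(s))` is the identity on canonical
generic SMILES.

Parsing, canonicalisation, descriptors, fingerprints, circular
fragments and 3D embedding are delegated to RDKit, driven in batch
through a bundled helper (`inst/python/chemtool.py`) so a whole corpus
costs one interpreter start-up. The test suite cross-checks descriptor
values against OpenBabel (via ChemmineR) as an independent engine.

## Sequence coding

SELFIES tokens are mapped one-to-one onto single printable characters
("molecular sequences"), with `!` reserved as the start marker and `E`
as the combined end-and-padding marker. One-hot vectorisation pads
every sequence to a fixed `embed` length; by default `embed` is the
longest training sequence plus the two marker positions, capped at 65
-- the cap is interpreted as the total padded length. Character
assignment is in sorted-token order, so an alphabet depends only on the
corpus's token *set*, and its JSON serialisation reloads bit-exactly.

## The encoder--decoder

A single-layer LSTM encoder reads the padded one-hot sequence and its
final hidden/cell pair `(h, c)` is the molecule's latent state; a
single-layer LSTM decoder, initialised with that state, is trained with
teacher forcing under categorical cross-entropy to re-emit the sequence
character by character (end-marker padding included, matching the
vectorised arrays). Generation decodes greedily -- argmax at each step,
stopping at `E` or at `embed - 2` characters -- so all diversity comes
from latent perturbation, not emission sampling.

Implementation choices that were genuinely open:

* **Backends.** The forward/backward pass exists twice: a reference
  implementation in plain R (`R/lstm.R`) and a compiled RcppArmadillo
  core (`src/lstm.cpp`) used for training. Both are cross-checked
  against each other to machine precision and against finite-difference
  gradients in the test suite.
* **Encoder input reversal** (`reverse_encoder = TRUE` by default): the
  encoder reads the sequence right to left, the classic trick that
  shortens the path between a sequence's head and the decoder's first
  emissions. It markedly improves reconstruction on this task.
* **Optimisation.** Adam (learning rate 0.01, batch size 10) with a
  multiplicative learning-rate decay of 0.99 per epoch and global-norm
  gradient clipping at 5. The decay stabilises the late,
  near-interpolation phase; without it training can destabilise after
  the loss approaches zero. The epoch budget defaults to 200.
* **Width.** `lstm_units = 128` by default. None of these four
  quantities is dictated by the method; they are exposed in
  `model_config()` and were fixed once from exploratory runs on the
  synthetic corpus described below.

## Generation by latent perturbation

For each seed active, the encoder produces `(h, c)`; independent
zero-mean noise with per-component scale equal to the chosen
*amplitude* (Gaussian by default, uniform available) is added to both
vectors, and the perturbed state is decoded. Defaults follow the
study design this package operationalises: amplitudes 0.1 and 0.2 with
20 samples per seed, so five seeds yield 100 raw samples per
amplitude. Candidates are canonicalised and deduplicated within each
amplitude first, then across amplitudes; seed molecules may
legitimately reappear. Because decoding is SELFIES-based, every raw
sample is a valid molecule -- the property the whole design leans on,
asserted as an invariant in the tests.

## The discriminator cascade and composite ranking

Three filters are applied in order (order provably irrelevant -- they
are independent predicates):

1. **QED ≥ 0.5** -- the quantitative estimate of drug-likeness, in
   [0, 1], consumed from RDKit's implementation;
2. **Lipinski's rule of 5** -- MW ≤ 500 g/mol, logP ≤ 5, H-bond donors
   ≤ 5, acceptors ≤ 10 (N+O convention), boundary values passing, zero
   violations by default (`max_violations = 1` gives the classic
   relaxed variant);
3. **Synthesizability ≥ 0**, with exactly 0 retained.

The synthesizability score is a Bernoulli naive-Bayes fragment sum: for
every circular fragment (Morgan environment, radius 2 by default) the
trained table stores
`ln((n_easy + p)/(N_easy + 2p)) − ln((n_hard + p)/(N_hard + 2p))`
with pseudocount `p = 1`, and a molecule scores the sum over its
distinct fragments; fragments never seen in training contribute the
corresponding smoothed unseen value. Positive means easier to make.
The package trains desk-scale tables on bundled synthetic easy
(chains, simple rings) and hard (fused, caged, spiro polycyclics)
sets; these separate the two training sets but are *not* a substitute
for a table trained on millions of molecules.

Ranking uses `my_score = 100 × (qed_norm + syn_norm)/2`, where both
normalisations are min--max over an explicitly stated reference set.
The reference defaults to the candidate pool being scored, is clipped
to [0, 1] for candidates outside it, and is recorded in the result --
normalised values are only comparable within one stated reference set,
so the choice is a parameter rather than an assumption. Seed actives
are picked from a ranked pool by the two-from-the-top,
two-from-the-middle, one-last rule, with "middle" read as the two
central ranks.

## Novelty audit and docking

Similarity uses the daylight-like hashed path fingerprint (paths up to
7 bonds, 2048 bits -- stated defaults, since nothing in the method pins
them) and the Tanimoto coefficient `|a∩b|/|a∪b|`, 1 for identical bit
vectors, with the two-empty-fingerprints case defined as 1.
`similarity_report()` emits the full pairwise matrix over ordered
pairs, min/mean/max, and histogram bins.

Docking is orchestration, not simulation: `dock_batch()` walks a
ligand × receptor grid behind a pluggable backend. The `vina` backend
drives an AutoDock Vina executable over prepared PDBQT files and
parses the best-pose affinity from its output table; receptor
preparation and the search box are deliberately explicit user inputs,
because results depend strongly on the search-space size. The `mock`
backend maps a hash of (canonical SMILES, receptor id) deterministically
into [−12, −4] kcal/mol so the entire pipeline is runnable and testable
with no external binary; its numbers are placeholders with the right
shape, nothing more. Ranking is by arithmetic mean energy across
receptors (ascending -- more negative is stronger), with per-receptor
minima reported; per-pair energies are reported to 0.1 kcal/mol and
means to 0.01. 3D structures for docking come from RDKit's ETKDG
embedding with explicit hydrogens and MMFF relaxation under a fixed
seed; molecules that fail to embed go to a skip report instead of
aborting the batch.

## The synthetic corpus: what it emulates and what it does not

`random_corpus()` draws uniform random token strings over a restricted
alphabet, decodes each (guaranteed valid), canonicalises, re-encodes to
the molecule's canonical SELFIES and keeps molecules whose token count
lies in the training window (30--50 by default), deduplicated. Random
derivations often stop before their token budget is spent, so raw
strings are drawn longer than the window and rejection-sampled; the
records' `token_length` therefore measures the canonical encoding and
tracks molecule size, as in a real length-filtered corpus.

Two deliberate choices:

* The default sampling alphabet is `[C] [N] [O] [S] [=C] [=N]
  [Branch1] [Ring1] [Ring2]`. `[F]` and `[=O]` are fully supported
  tokens but are excluded from the *default* because on the main chain
  they saturate the current atom and terminate derivation, collapsing
  random corpora into tiny duplicate molecules and destroying the
  length window. Any alphabet can be supplied.
* Fixture corpora emulate the *statistical shape* of a drug-like
  training set (size window, token inventory, uniqueness), not real
  chemistry: no aromatic heterocycle bias, no functional-group
  distribution, no synthetic tractability. Tests passing on them show
  the machinery is correct, not that the model generates medicinal
  chemistry.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: the reconstruction
experiment trains on 100 synthetic molecules of 30--50 tokens for the
full 200-epoch budget (about two minutes with the compiled core) and
then requires at least 90% exact greedy reconstruction; the round-trip
identity is exercised on 1,000 random fixtures; split arithmetic is
checked on a 121,000-record corpus. Softmax is computed with max
subtraction; probabilities are floored at 1e-12 inside the loss;
min--max normalisation treats a constant reference as an error except
for the single-candidate convention (0). The derivation clamps
out-of-range ring targets to the first atom and skips duplicate ring
bonds; both rules matter only for adversarial strings, since the
encoder never emits them.

## Known limitations

* The SELFIES dialect excludes charges, isotopes, radicals and
  stereochemistry; corpus preparation drops such molecules with an
  explicit count rather than silently corrupting them.
* Greedy decoding plus latent noise explores a *local* neighbourhood of
  each seed; the model cannot steer toward a target profile and cannot
  judge biological activity -- the cascade and docking stages exist
  precisely because the generator cannot.
* Sequences longer than `embed − 2` characters (default cap 65) cannot
  be represented; that bounds molecule size.
* The mock docking backend is deterministic noise with the right range;
  any scientific use of binding energies requires the Vina backend with
  prepared receptors.
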