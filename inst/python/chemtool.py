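#!/usr/bin/env python
"""Batch chemistry backend for the selfgen R package.

Reads one JSON request object on stdin and writes one JSON response to
stdout.  All operations are vectorised over molecules so that a whole
corpus costs a single interpreter start-up.  Per-molecule failures are
reported in-band (result null + error string); the process only exits
non-zero on malformed requests.
"""

import json
import sys


def _mol(smiles):
    from rdkit import Chem
    m = Chem.MolFromSmiles(smiles)
    if m is None:
        raise ValueError("unparsable SMILES: %r" % smiles)
    return m


def op_canonical(req):
    """Canonical generic (stereo-free) SMILES."""
    from rdkit import Chem
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = _mol(smi)
            Chem.RemoveStereochemistry(m)
            out.append(Chem.MolToSmiles(m, isomericSmiles=False))
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err}


def op_graph(req):
    """Kekulized heavy-atom graph: element/charge/isotope per atom,
    (begin, end, order) per bond.  1-based atom indices."""
    from rdkit import Chem
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = _mol(smi)
            Chem.Kekulize(m, clearAromaticFlags=True)
            atoms = [{"element": a.GetSymbol(),
                      "charge": a.GetFormalCharge(),
                      "isotope": a.GetIsotope(),
                      "radical": a.GetNumRadicalElectrons(),
                      "hs": a.GetTotalNumHs()}
                     for a in m.GetAtoms()]
            bonds = [{"a1": b.GetBeginAtomIdx() + 1,
                      "a2": b.GetEndAtomIdx() + 1,
                      "order": int(b.GetBondTypeAsDouble())}
                     for b in m.GetBonds()]
            out.append({"atoms": atoms, "bonds": bonds})
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err}


def op_panel(req):
    """Descriptor panel: MW, Crippen logP, Lipinski N+O H-bond counts, QED."""
    from rdkit.Chem import Crippen, Descriptors, Lipinski, QED
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = _mol(smi)
            out.append({"mw": Descriptors.MolWt(m),
                        "logp": Crippen.MolLogP(m),
                        "hbd": Lipinski.NHOHCount(m),
                        "hba": Lipinski.NOCount(m),
                        "qed": QED.qed(m)})
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err}


def op_fingerprint(req):
    """RDKit path-based (daylight-like) fingerprint; on-bit positions, 0-based."""
    from rdkit import Chem
    n_bits = int(req.get("n_bits", 2048))
    max_path = int(req.get("max_path", 7))
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = _mol(smi)
            fp = Chem.RDKFingerprint(m, maxPath=max_path, fpSize=n_bits)
            out.append(sorted(fp.GetOnBits()))
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err, "n_bits": n_bits}


def op_fragments(req):
    """Distinct hashed circular-fragment (Morgan environment) identifiers
    up to the requested radius, as strings (hashes exceed 2^31)."""
    from rdkit.Chem import AllChem
    radius = int(req.get("radius", 2))
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = _mol(smi)
            fp = AllChem.GetMorganFingerprint(m, radius)
            out.append(sorted(str(k) for k in fp.GetNonzeroElements()))
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err, "radius": radius}


def op_embed3d(req):
    """ETKDG 3D embedding with explicit hydrogens; MMFF-relaxed when the
    force field is available.  Deterministic for a fixed seed."""
    from rdkit import Chem
    from rdkit.Chem import AllChem
    seed = int(req.get("seed", 7))
    optimize = bool(req.get("optimize", True))
    out, err = [], []
    for smi in req["smiles"]:
        try:
            m = Chem.AddHs(_mol(smi))
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            code = AllChem.EmbedMolecule(m, params)
            if code != 0:
                raise ValueError("3D embedding failed for %r" % smi)
            if optimize:
                try:
                    AllChem.MMFFOptimizeMolecule(m, maxIters=500)
                except Exception:  # noqa: BLE001
                    pass
            out.append({"molblock": Chem.MolToMolBlock(m),
                        "n_atoms": m.GetNumAtoms()})
            err.append(None)
        except Exception as e:  # noqa: BLE001
            out.append(None)
            err.append(str(e))
    return {"result": out, "error": err, "seed": seed}


def op_version(req):
    import rdkit
    return {"result": rdkit.__version__, "error": None}


OPS = {
    "canonical": op_canonical,
    "graph": op_graph,
    "panel": op_panel,
    "fingerprint": op_fingerprint,
    "fragments": op_fragments,
    "embed3d": op_embed3d,
    "version": op_version,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"ok": False, "message": "unknown op: %r" % op, "result": None},
                  sys.stdout)
        return 2
    try:
        resp = OPS[op](req)
    except Exception as e:  # noqa: BLE001
        json.dump({"ok": False, "message": str(e), "result": None}, sys.stdout)
        return 1
    resp["ok"] = True
    json.dump(resp, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
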