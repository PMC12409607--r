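"""RDKit worker for the smilesaugment R package.

Called as:  python rdkit_bridge.py <request.json> <response.json>

The request is a JSON object {"op": <name>, ...op-specific fields...}; the
response is a JSON object with parallel arrays.  Every operation is batched
over a list of SMILES and never raises on a bad molecule: per-molecule
failures are reported through "valid"/"ok" flags so the R side can decide.
All randomness is injected from R as explicit integer seeds.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, BRICS, Descriptors, rdMolDescriptors
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def _mol(smiles):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles)


def op_canonicalize(req):
    out = {"valid": [], "canonical": []}
    for s in req["smiles"]:
        m = _mol(s)
        out["valid"].append(m is not None)
        out["canonical"].append(Chem.MolToSmiles(m) if m is not None else None)
    return out


def op_randomize(req):
    n = int(req["n_variants"])
    out = {"valid": [], "variants": []}
    for s, seed in zip(req["smiles"], req["seeds"]):
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["variants"].append([])
            continue
        if m.GetNumAtoms() <= 1:
            vs = [Chem.MolToSmiles(m)] * n
        else:
            vs = list(Chem.MolToRandomSmilesVect(m, n, randomSeed=int(seed)))
        out["valid"].append(True)
        out["variants"].append(vs)
    return out


def op_descriptors(req):
    cols = ("n_aliphatic_rings", "n_aromatic_rings", "mw", "logp", "hbd",
            "hba", "tpsa", "n_rotatable_bonds")
    out = {"valid": []}
    for c in cols:
        out[c] = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            for c in cols:
                out[c].append(None)
            continue
        out["valid"].append(True)
        out["n_aliphatic_rings"].append(rdMolDescriptors.CalcNumAliphaticRings(m))
        out["n_aromatic_rings"].append(rdMolDescriptors.CalcNumAromaticRings(m))
        out["mw"].append(Descriptors.MolWt(m))
        out["logp"].append(Descriptors.MolLogP(m))
        out["hbd"].append(rdMolDescriptors.CalcNumHBD(m))
        out["hba"].append(rdMolDescriptors.CalcNumHBA(m))
        out["tpsa"].append(Descriptors.TPSA(m))
        out["n_rotatable_bonds"].append(rdMolDescriptors.CalcNumRotatableBonds(m))
    return out


def op_scaffold(req):
    generic = bool(req.get("generic", False))
    out = {"valid": [], "scaffold": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["scaffold"].append(None)
            continue
        try:
            sc = MurckoScaffold.GetScaffoldForMol(m)
            if generic and sc.GetNumAtoms() > 0:
                sc = MurckoScaffold.MakeScaffoldGeneric(sc)
            out["valid"].append(True)
            out["scaffold"].append(Chem.MolToSmiles(sc))
        except Exception:
            out["valid"].append(False)
            out["scaffold"].append(None)
    return out


def _fp(m, radius, n_bits):
    return AllChem.GetMorganFingerprintAsBitVect(m, int(radius), nBits=int(n_bits))


def op_fingerprint_bits(req):
    out = {"valid": [], "bits": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["bits"].append([])
            continue
        out["valid"].append(True)
        out["bits"].append(list(_fp(m, req["radius"], req["n_bits"]).GetOnBits()))
    return out


def op_tanimoto_matrix(req):
    from rdkit import DataStructs
    fps, valid = [], []
    for s in req["smiles"]:
        m = _mol(s)
        valid.append(m is not None)
        fps.append(_fp(m, req["radius"], req["n_bits"]) if m is not None else None)
    n = len(fps)
    mat = [[None] * n for _ in range(n)]
    for i in range(n):
        if fps[i] is None:
            continue
        mat[i][i] = 1.0
        for j in range(i + 1, n):
            if fps[j] is None:
                continue
            t = DataStructs.TanimotoSimilarity(fps[i], fps[j])
            mat[i][j] = t
            mat[j][i] = t
    return {"valid": valid, "matrix": mat}


def op_atom_info(req):
    out = {"valid": [], "n_atoms": [], "elements": [], "aromatic": [],
           "in_order": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["n_atoms"].append(0)
            out["elements"].append([])
            out["aromatic"].append([])
            out["in_order"].append(None)
            continue
        out["valid"].append(True)
        out["n_atoms"].append(m.GetNumAtoms())
        out["elements"].append([a.GetSymbol() for a in m.GetAtoms()])
        out["aromatic"].append([a.GetIsAromatic() for a in m.GetAtoms()])
        out["in_order"].append(Chem.MolToSmiles(m, canonical=False))
    return out


def op_smarts_matches(req):
    pats = []
    pat_ok = []
    for p in req["smarts"]:
        q = Chem.MolFromSmarts(p)
        pats.append(q)
        pat_ok.append(q is not None)
    out = {"valid": [], "pattern_ok": pat_ok, "matches": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["matches"].append([[] for _ in pats])
            continue
        out["valid"].append(True)
        row = []
        for q in pats:
            if q is None:
                row.append([])
            else:
                row.append([list(t) for t in m.GetSubstructMatches(q)])
        out["matches"].append(row)
    return out


def op_mask(req):
    """Replace the atoms at the given 0-based indices by the dummy atom '*'.

    The masked SMILES is emitted in input atom order (canonical=False) so it
    aligns token-by-token with the in-order rendering of the source."""
    out = {"ok": [], "masked": [], "orig_in_order": [], "n_atoms": []}
    for s, idx in zip(req["smiles"], req["masked"]):
        m = _mol(s)
        if m is None:
            out["ok"].append(False)
            out["masked"].append(None)
            out["orig_in_order"].append(None)
            out["n_atoms"].append(0)
            continue
        try:
            em = Chem.RWMol(m)
            for i in idx:
                a = em.GetAtomWithIdx(int(i))
                a.SetAtomicNum(0)
                a.SetFormalCharge(0)
                a.SetNumExplicitHs(0)
                a.SetNoImplicit(True)
            # aromatic bonds between two dummies would print as explicit
            # ':' tokens and break alignment with the source string
            for b in em.GetBonds():
                if (b.GetIsAromatic()
                        and b.GetBeginAtom().GetAtomicNum() == 0
                        and b.GetEndAtom().GetAtomicNum() == 0):
                    b.SetIsAromatic(False)
                    b.SetBondType(Chem.BondType.SINGLE)
            out["ok"].append(True)
            out["masked"].append(Chem.MolToSmiles(em, canonical=False))
            out["orig_in_order"].append(Chem.MolToSmiles(m, canonical=False))
            out["n_atoms"].append(m.GetNumAtoms())
        except Exception:
            out["ok"].append(False)
            out["masked"].append(None)
            out["orig_in_order"].append(None)
            out["n_atoms"].append(0)
    return out


def _brics_fragments(m):
    """Cut all BRICS bonds; returns (frag mol list, per-fragment dummy labels).

    Bond k (1-based) contributes dummy atoms with isotope k on both sides, so
    reassembly is a molzip over isotope-matched attachment points."""
    bonds = list(BRICS.FindBRICSBonds(m))
    if not bonds:
        return [Chem.Mol(m)], [[]]
    bidx = [m.GetBondBetweenAtoms(a, b).GetIdx() for (a, b), _ in bonds]
    labels = [(k + 1, k + 1) for k in range(len(bidx))]
    cut = Chem.FragmentOnBonds(m, bidx, dummyLabels=labels)
    frags = list(Chem.GetMolFrags(cut, asMols=True, sanitizeFrags=False))
    dummy = []
    for f in frags:
        labs = sorted(a.GetIsotope() for a in f.GetAtoms() if a.GetAtomicNum() == 0)
        dummy.append(labs)
    return frags, dummy


def _frag_key(f):
    """Canonical fragment key: attachment isotopes stripped to bare '*'."""
    g = Chem.RWMol(f)
    for a in g.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetIsotope(0)
    return Chem.MolToSmiles(g.GetMol())


def op_brics_decompose(req):
    out = {"valid": [], "frags": [], "keys": [], "arity": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["frags"].append([])
            out["keys"].append([])
            out["arity"].append([])
            continue
        frags, dummy = _brics_fragments(m)
        out["valid"].append(True)
        out["frags"].append([Chem.MolToSmiles(f) for f in frags])
        out["keys"].append([_frag_key(f) for f in frags])
        out["arity"].append([len(d) for d in dummy])
    return out


def op_fragment_key(req):
    out = {"valid": [], "key": [], "arity": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["key"].append(None)
            out["arity"].append(0)
            continue
        out["valid"].append(True)
        out["key"].append(_frag_key(m))
        out["arity"].append(sum(1 for a in m.GetAtoms() if a.GetAtomicNum() == 0))
    return out


def _zip_fragments(frags):
    combo = frags[0]
    for f in frags[1:]:
        combo = Chem.CombineMols(combo, f)
    params = Chem.MolzipParams()
    params.label = Chem.MolzipLabel.Isotope
    return Chem.molzip(combo, params)


def op_brics_reassemble(req):
    out = {"ok": [], "smiles": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["ok"].append(False)
            out["smiles"].append(None)
            continue
        try:
            frags, _ = _brics_fragments(m)
            z = _zip_fragments(frags)
            Chem.SanitizeMol(z)
            out["ok"].append(True)
            out["smiles"].append(Chem.MolToSmiles(z))
        except Exception:
            out["ok"].append(False)
            out["smiles"].append(None)
    return out


def op_brics_substitute(req):
    """Replace selected BRICS fragments and re-zip.

    req["repl"][i] is a list of {"idx": fragment index (0-based, in the order
    reported by brics_decompose), "rep": replacement fragment SMILES with
    [1*],[2*],... attachment labels}.  Replacement attachment point k (by
    ascending label) inherits the k-th (ascending) bond isotope of the
    fragment it replaces."""
    out = {"ok": [], "smiles": []}
    for s, repl in zip(req["smiles"], req["repl"]):
        m = _mol(s)
        if m is None or not repl:
            out["ok"].append(False)
            out["smiles"].append(None)
            continue
        try:
            frags, dummy = _brics_fragments(m)
            frags = [Chem.RWMol(f).GetMol() for f in frags]
            failed = False
            for r in repl:
                i = int(r["idx"])
                rep = Chem.MolFromSmiles(r["rep"])
                if rep is None:
                    failed = True
                    break
                rd = sorted((a.GetIsotope(), a.GetIdx()) for a in rep.GetAtoms()
                            if a.GetAtomicNum() == 0)
                if len(rd) != len(dummy[i]):
                    failed = True
                    break
                rw = Chem.RWMol(rep)
                for (lab, aidx), iso in zip(rd, dummy[i]):
                    rw.GetAtomWithIdx(aidx).SetIsotope(int(iso))
                frags[i] = rw.GetMol()
            if failed:
                out["ok"].append(False)
                out["smiles"].append(None)
                continue
            z = _zip_fragments(frags)
            if any(a.GetAtomicNum() == 0 for a in z.GetAtoms()):
                raise ValueError("unzipped attachment point")
            Chem.SanitizeMol(z)
            out["ok"].append(True)
            out["smiles"].append(Chem.MolToSmiles(z))
        except Exception:
            out["ok"].append(False)
            out["smiles"].append(None)
    return out


def op_curate(req):
    """Desalt (largest fragment), neutralize charges, strip stereo, sanitize."""
    uncharger = rdMolStandardize.Uncharger()
    out = {"valid": [], "canonical": [], "elements": [], "had_salt": [],
           "had_charge": [], "had_stereo": []}
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out["valid"].append(False)
            out["canonical"].append(None)
            out["elements"].append([])
            out["had_salt"].append(False)
            out["had_charge"].append(False)
            out["had_stereo"].append(False)
            continue
        try:
            frags = Chem.GetMolFrags(m, asMols=True)
            had_salt = len(frags) > 1
            m = max(frags, key=lambda f: f.GetNumAtoms())
            had_charge = any(a.GetFormalCharge() != 0 for a in m.GetAtoms())
            m = uncharger.uncharge(m)
            had_stereo = "@" in s or "/" in s or "\\" in s
            Chem.RemoveStereochemistry(m)
            Chem.SanitizeMol(m)
            out["valid"].append(True)
            out["canonical"].append(Chem.MolToSmiles(m))
            out["elements"].append([a.GetSymbol() for a in m.GetAtoms()])
            out["had_salt"].append(had_salt)
            out["had_charge"].append(had_charge)
            out["had_stereo"].append(had_stereo)
        except Exception:
            out["valid"].append(False)
            out["canonical"].append(None)
            out["elements"].append([])
            out["had_salt"].append(False)
            out["had_charge"].append(False)
            out["had_stereo"].append(False)
    return out


OPS = {
    "canonicalize": op_canonicalize,
    "randomize": op_randomize,
    "descriptors": op_descriptors,
    "scaffold": op_scaffold,
    "fingerprint_bits": op_fingerprint_bits,
    "tanimoto_matrix": op_tanimoto_matrix,
    "atom_info": op_atom_info,
    "smarts_matches": op_smarts_matches,
    "mask": op_mask,
    "brics_decompose": op_brics_decompose,
    "brics_reassemble": op_brics_reassemble,
    "brics_substitute": op_brics_substitute,
    "fragment_key": op_fragment_key,
    "curate": op_curate,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req.get("op")
    if op not in OPS:
        raise SystemExit("unknown op: %r" % op)
    res = OPS[op](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
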