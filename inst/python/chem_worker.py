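"""RDKit worker for the molsculpt R package.

Speaks a JSON-line protocol over a localhost TCP socket: one request object
per line in, one response object per line out.  Requests are
{"id": n, "cmd": str, "args": {...}}; responses {"id": n, "ok": bool,
"result"/"error": ...}.  All molecule-level commands are batched over a list
of SMILES and return null for entries RDKit cannot parse.
"""
import json
import math
import os
import socket
import sys

from rdkit import Chem, RDLogger, DataStructs
from rdkit.Chem import QED, Crippen, Descriptors, rdMolDescriptors, AllChem
from rdkit.Chem import RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def _mol(smi):
    if not isinstance(smi, str):
        return None
    return Chem.MolFromSmiles(smi)


def _per_mol(smiles, fn):
    out = []
    for smi in smiles:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        try:
            out.append(fn(m))
        except Exception:
            out.append(None)
    return out


def cmd_ping(args):
    return "pong"


def cmd_valid(args):
    # an empty mol (zero atoms) is not a molecule
    return [(m := _mol(s)) is not None and m.GetNumAtoms() > 0
            for s in args["smiles"]]


def cmd_canonical(args):
    return _per_mol(args["smiles"], Chem.MolToSmiles)


def cmd_qed(args):
    return _per_mol(args["smiles"], QED.qed)


def cmd_qed_detail(args):
    def detail(m):
        p = QED.properties(m)
        return {"MW": p.MW, "ALOGP": p.ALOGP, "HBA": p.HBA, "HBD": p.HBD,
                "PSA": p.PSA, "ROTB": p.ROTB, "AROM": p.AROM,
                "ALERTS": p.ALERTS}
    return _per_mol(args["smiles"], detail)


def cmd_qed_params(args):
    # ADS parameter sets (a..f, dmax) and the mean-weighting scheme, exposed
    # so a caller can recompute QED from raw properties independently.
    names = ["MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"]
    params = {}
    for k in names:
        ads = QED.adsParameters[k]
        params[k] = {"A": ads.A, "B": ads.B, "C": ads.C, "D": ads.D,
                     "E": ads.E, "F": ads.F, "DMAX": ads.DMAX}
    return {"params": params, "weights_mean": list(QED.WEIGHT_MEAN),
            "order": names}


def cmd_logp(args):
    return _per_mol(args["smiles"], Crippen.MolLogP)


def cmd_logp_contribs(args):
    def contribs(m):
        cs = rdMolDescriptors._CalcCrippenContribs(Chem.AddHs(m))
        return [c[0] for c in cs]
    return _per_mol(args["smiles"], contribs)


def cmd_sa(args):
    return _per_mol(args["smiles"], sascorer.calculateScore)


def cmd_sa_detail(args):
    # Raw ingredients of the Ertl-Schuffenhauer score so the aggregation can
    # be recomputed outside this process.
    def detail(m):
        fp = rdMolDescriptors.GetMorganFingerprint(m, 2)
        bits = sorted(fp.GetNonzeroElements().items())
        fscores = [sascorer._fscores.get(b, -4) if sascorer._fscores else None
                   for b, _ in bits]
        ri = m.GetRingInfo()
        return {
            "bit_ids": [b for b, _ in bits],
            "bit_counts": [c for _, c in bits],
            "fscores": fscores,
            "natoms": m.GetNumAtoms(),
            "nchiral": len(Chem.FindMolChiralCenters(m, includeUnassigned=True)),
            "nbridge": rdMolDescriptors.CalcNumBridgeheadAtoms(m),
            "nspiro": rdMolDescriptors.CalcNumSpiroAtoms(m),
            "nmacro": sum(1 for r in ri.AtomRings() if len(r) > 8),
        }
    if sascorer._fscores is None:
        sascorer.readFragmentScores()
    return _per_mol(args["smiles"], detail)


def cmd_ring_sizes(args):
    def sizes(m):
        return [len(r) for r in m.GetRingInfo().AtomRings()]
    return _per_mol(args["smiles"], sizes)


def cmd_morgan_bits(args):
    nbits = int(args.get("nbits", 2048))
    def bits(m):
        fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(m, 2, nBits=nbits)
        return list(fp.GetOnBits())
    return _per_mol(args["smiles"], bits)


def cmd_tanimoto(args):
    ma, mb = _mol(args["a"]), _mol(args["b"])
    if ma is None or mb is None:
        return None
    fa = rdMolDescriptors.GetMorganFingerprintAsBitVect(ma, 2, nBits=2048)
    fb = rdMolDescriptors.GetMorganFingerprintAsBitVect(mb, 2, nBits=2048)
    return DataStructs.TanimotoSimilarity(fa, fb)


COMMANDS = {name[4:]: fn for name, fn in list(globals().items())
            if name.startswith("cmd_")}


def main():
    port = int(sys.argv[1])
    sock = socket.create_connection(("127.0.0.1", port))
    rfile = sock.makefile("r", encoding="utf-8")
    wfile = sock.makefile("w", encoding="utf-8")
    for line in rfile:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("cmd") == "shutdown":
                break
            fn = COMMANDS[req["cmd"]]
            res = {"id": req.get("id"), "ok": True,
                   "result": fn(req.get("args", {}))}
        except Exception as exc:  # report, never die mid-protocol
            res = {"id": req.get("id") if isinstance(req, dict) else None,
                   "ok": False, "error": f"{type(exc).__name__}: {exc}"}
        wfile.write(json.dumps(res) + "\n")
        wfile.flush()
    sock.close()


if __name__ == "__main__":
    main()
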