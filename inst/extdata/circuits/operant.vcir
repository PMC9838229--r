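# Operant conditioning through disinhibition: at the start the pathway from
# watch to spot is open and the pathways to the accept/reject effectors are
# closed. The spot thread discriminates the reinforcement (excite/inhibit);
# LTP opens the path to accept or reject, LTD closes the path to spot,
# leaving a learned deterministic response.
circuit operant
stream s
node sensor s s_watch watch(I)
node internal s spotd spot(I)
node effector s accept accept(I)
node effector s reject reject(I)
node sensor s s_exc excite
node sensor s s_inh inhibit
edge synapse s_watch spotd w=1
edge synapse s_watch accept w=0
edge synapse s_watch reject w=0
edge modulation s_exc s_watch>accept plasticity=ltp
edge modulation s_inh s_watch>reject plasticity=ltp
edge modulation s_exc s_watch>spotd plasticity=ltd
edge modulation s_inh s_watch>spotd plasticity=ltd
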