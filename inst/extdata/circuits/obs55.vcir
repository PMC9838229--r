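# Sensory-motor substage 5 (observation 55): partially invisible
# displacement. Extends the searching circuit with a practical-learning
# sub-circuit implemented as operant conditioning: the stop of the box
# drives a watch thread (sustained for the trial); spotting the box empty
# drives a fail thread. The conjunction watch * fail gates a recall thread
# through a pathway that is closed at the start and opened by an LTP whose
# trigger is the excite reinforcement following a successful grasp. The
# recall, once learned, pops the remembered position <look(Q(X+1))> where
# the object disappeared (pushed by the look thread, FIFO) and drives a
# renewed search there.
circuit obs55
stream main
node sensor main s_move move(obj(P,X))
node internal main expect expect(obj(P,X+1)) ttl=2
node sensor main s_see see(obj(Q,X+1))
node internal main cont cont(obj(P,X+1)) ttl=2
node internal main divert divert(obj(Q,X+1))
node sensor main s_halt halt(T)
node effector main grasp grasp(obj(P,X+1))
node effector main look look(obj(Q,X+1)) plasticity=push:looks
node effector main search search(T)
node sensor main s_view view(obj(P,X))
node sensor main s_stop stop(box(F,X))
node internal main watch watch(box(F,X)) ttl=8
node internal main spotd spot(box(F,X))
node sensor main s_failbox spot(box(F,empty,X))
node internal main fail fail(box(F,X))
node internal main recall recall(box(F,X))
node sensor main s_exc excite
edge synapse s_move expect
edge conj expect cont w=0 plasticity=stp:expect:2 choice=attend
edge conj s_see cont as=see(obj(P,X+1))
edge conj expect divert w=0 plasticity=stp:expect:2 as=expect(obj(P0,X+1)) choice=attend
edge conj s_see divert
edge synapse divert look
edge conj cont grasp
edge conj s_halt grasp as=halt(obj(P,X+1))
edge synapse s_halt search w=0 plasticity=ltp:divert
edge synapse s_view grasp w=0 payload=grasp(obj(P,X)) plasticity=stp:search:2
edge synapse s_stop watch
edge synapse watch spotd w=1
edge modulation s_exc watch>spotd plasticity=ltd
edge synapse s_failbox fail
edge conj watch recall w=0 plasticity=ltp:s_exc
edge conj fail recall
edge synapse recall search pop=looks:look(Q) payload=search(Q)
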